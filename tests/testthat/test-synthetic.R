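test_that("generators are byte-deterministic under the seed", {
  spec <- syntheticSpec(seed = 17L, nProteins = 5L,
                        lengthRange = c(100L, 140L))
  p1 <- withr::local_tempfile(fileext = ".fasta")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  writeFastaRecords(genProteome(spec)$records, p1)
  writeFastaRecords(genProteome(spec)$records, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  other <- genProteome(syntheticSpec(seed = 18L, nProteins = 5L,
                                     lengthRange = c(100L, 140L)))
  writeFastaRecords(other$records, p2)
  expect_false(identical(readBin(p1, "raw", file.size(p1)),
                         readBin(p2, "raw", file.size(p2))))
})

test_that("zero density implants nothing and short ranges error", {
  sim <- genProteome(syntheticSpec(seed = 1L, nProteins = 3L,
                                   lengthRange = c(50L, 60L),
                                   motifDensity = 0))
  expect_identical(nrow(sim$truth), 0L)
  expect_error(genProteome(syntheticSpec(seed = 1L, nProteins = 1L,
                                         lengthRange = c(5L, 6L))),
               "too short")
})

test_that("every implanted motif is recovered by the scanner", {
  spec <- syntheticSpec(seed = 23L, nProteins = 30L,
                        lengthRange = c(300L, 600L))
  sim <- genProteome(spec)
  expect_gt(nrow(sim$truth), 0L)
  hits <- scanMotifs(sim$records)
  found <- vapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    any(hits$protein_id == tr$protein_id & hits$start == tr$start &
        hits$matched == tr$window &
        grepl(tr$submotif, hits$submotifs))
  }, logical(1))
  expect_true(all(found))    # 100% recall by construction
})

test_that("implant counts stay inside the central 99% Poisson band", {
  spec <- syntheticSpec(seed = 29L, nProteins = 150L,
                        lengthRange = c(300L, 400L), motifDensity = 1)
  sim <- genProteome(spec)
  lambda <- 150
  band <- qpois(c(0.005, 0.995), lambda)
  expect_gte(nrow(sim$truth), band[1])
  expect_lte(nrow(sim$truth), band[2])
})

test_that("single-violation decoys are never matched", {
  dec <- genDecoys(200L, seed = 31L)
  hits <- scanMotifs(dec$records, motifDefinitions("general"))
  expect_identical(nrow(hits), 0L)
  ## all four constrained positions are probed
  expect_setequal(unique(dec$truth$violated_position), c(1L, 2L, 5L, 6L))
  ## the published probes: Leu at Psi, Ala at beta
  expect_identical(nrow(scanMotifs(proteinRecord("psiL", "GGLVASQPGG"))), 0L)
  expect_identical(nrow(scanMotifs(proteinRecord("betaA", "GGVAASQPGG"))), 0L)
  ## submotif scanning finds nothing either
  hits_sub <- scanMotifs(dec$records, motifDefinitions("submotifs"))
  expect_identical(nrow(hits_sub), 0L)
})

test_that("conservation calls track the ortholog-generator truth", {
  n_ok <- 0L
  for (seed in 1:100) {
    preserve <- seed %% 2L == 0L
    spec <- syntheticSpec(seed = seed, nProteins = 1L,
                          lengthRange = c(100L, 130L), motifDensity = 1,
                          orthologSubstRate = 0.1,
                          preserveMotif = preserve)
    sim <- genProteome(spec)
    if (!nrow(sim$truth)) next
    rec <- Filter(function(r) proteinId(r) == sim$truth$protein_id[1],
                  sim$records)[[1]]
    trip <- genOrthologTriple(rec, spec)
    cc <- motifConserved(trip$set, trip$hit)
    expect_identical(cc$motif_conserved, trip$truth$preserved,
                     info = paste("seed", seed))
    n_ok <- n_ok + 1L
  }
  expect_gt(n_ok, 50L)   # most seeds carry an implanted motif
})

test_that("rate-zero preserved orthologs are identical and conserved", {
  spec <- syntheticSpec(seed = 37L, nProteins = 1L,
                        lengthRange = c(100L, 100L), motifDensity = 1,
                        orthologSubstRate = 0, preserveMotif = TRUE)
  sim <- genProteome(spec)
  rec <- Filter(function(r) proteinId(r) == sim$truth$protein_id[1],
                sim$records)[[1]]
  trip <- genOrthologTriple(rec, spec)
  for (o in trip$set@orthologs)
    expect_identical(proteinSeq(o), proteinSeq(rec))
  expect_true(motifConserved(trip$set, trip$hit)$motif_conserved)
})

test_that("engineered candidate tables reproduce their target stage counts", {
  spec <- syntheticSpec(seed = 41L, cascadeTargets = c(17L, 15L, 14L))
  sim <- genCandidateTable(spec, nNonMotif = 3L)
  report <- runCascade(sim$candidates)
  expect_identical(unname(stageCounts(report)), c(17L, 15L, 14L))
  expect_identical(length(finalSet(report)), 14L)
  expect_identical(unname(stageCounts(report)),
                   unname(sim$expected$stage_counts))
  ## all-pass and all-empty edge cases
  all5 <- genCandidateTable(syntheticSpec(seed = 43L,
                                          cascadeTargets = c(5L, 5L, 5L)))
  r5 <- runCascade(all5$candidates)
  expect_identical(unname(stageCounts(r5)), c(5L, 5L, 5L))
  expect_identical(length(finalSet(r5)), 5L)
  zero <- genCandidateTable(syntheticSpec(seed = 47L,
                                          cascadeTargets = c(0L, 0L, 0L)))
  r0 <- runCascade(zero$candidates)
  expect_identical(unname(stageCounts(r0)), c(0L, 0L, 0L))
  expect_identical(nrow(reportRows(r0)), 0L)
  ## increasing targets are rejected by the spec validity rules
  expect_error(syntheticSpec(seed = 1L, cascadeTargets = c(5L, 6L, 4L)),
               "non-increasing")
})
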