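test_that("the SNAP25b decapeptide yields its single published hit", {
  rec <- proteinRecord("SNAP25b_111-120", "GVVASQPARV", offset = 111)
  hits <- scanMotifs(rec)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 112L)
  expect_identical(hits$end, 117L)
  expect_identical(hits$matched, "VVASQP")
  expect_true(hits$general)
  expect_identical(hits$submotifs, "submotif1")
  expect_identical(hits$qualifier, "full")
})

test_that("motif-free sequences yield an empty hit frame", {
  polyA <- proteinRecord("polyA", strrep("A", 50))
  hits <- scanMotifs(polyA)
  expect_identical(nrow(hits), 0L)
  expect_named(hits, c("protein_id", "start", "end", "matched", "general",
                       "submotifs", "context_ok", "qualifier"))
  expect_error(proteinRecord("empty", ""), "non-empty")
})

test_that("scanner agrees with a brute-force window oracle on random sequences", {
  set.seed(2024)
  gen <- motifDefinitions("general")
  for (i in seq_len(200)) {
    s <- randomSeq(500)
    hits <- scanMotifs(proteinRecord("r", s), gen)
    expect_identical(hits$start, oracleGeneralStarts(s),
                     info = paste("sequence", i))
  }
})

test_that("hit coordinates shift exactly with the numbering offset", {
  set.seed(5)
  s <- paste0(randomSeq(40), "QVTMTQP", randomSeq(40), "VVASQP", randomSeq(10))
  base <- scanMotifs(proteinRecord("p", s, offset = 1))
  for (k in c(2L, 50L, 111L)) {
    shifted <- scanMotifs(proteinRecord("p", s, offset = k))
    expect_identical(shifted$start, base$start + (k - 1L))
    expect_identical(shifted$end, base$end + (k - 1L))
    expect_identical(shifted$matched, base$matched)
  }
})

test_that("submotif-3 context is reported and denied at the sequence start", {
  ## VTMTQP at the very start has no upstream residue: the context-requiring
  ## submotif cannot fire (the context-free general consensus still does)
  hits <- scanMotifs(proteinRecord("p", "VTMTQPAAA"),
                     motifDefinitions("submotifs"))
  expect_identical(nrow(hits), 0L)
  gen_only <- scanMotifs(proteinRecord("p", "VTMTQPAAA"))
  expect_identical(gen_only$submotifs, "")
  expect_false(gen_only$context_ok)
  ## with the upstream Gln present the same window is a submotif-3 hit
  hits2 <- scanMotifs(proteinRecord("p", "QVTMTQPAAA"))
  expect_identical(nrow(hits2), 1L)
  expect_identical(hits2$start, 2L)
  expect_true(hits2$context_ok)
  expect_match(hits2$submotifs, "submotif3")
})

test_that("mutation labels parse and malformed ones fail", {
  m <- parseMutation("V112A")
  expect_identical(m$position, 112L)
  expect_identical(m$wildType, "V")
  expect_identical(m$substituted, "A")
  expect_identical(parseMutation("T496A")$position, 496L)
  expect_error(parseMutation("117A"), "malformed")
  expect_error(parseMutation("V112"), "malformed")
  expect_error(parseMutation("VA"), "malformed")
})

test_that("mutation application checks the wild type against the sequence", {
  rec <- proteinRecord("SNAP25b_111-120", "GVVASQPARV", offset = 111)
  mut <- applyMutation(rec, "P117A")
  expect_identical(proteinSeq(mut), "GVVASQAARV")
  expect_error(applyMutation(rec, "Q117A"), "wild-type mismatch")
  expect_error(applyMutation(rec, "P300A"), "outside")
})

test_that("alanine-scan calls match the published concordance suites", {
  snap <- proteinRecord("SNAP25b_111-120", "GVVASQPARV", offset = 111)
  snap_panel <- c("V112A", "V113A", "Q116A", "P117A")
  snap_effects <- vapply(snap_panel, function(m)
    predictMutationEffect(snap, m)$effect, character(1))
  expect_identical(names(snap_effects)[snap_effects == "lost"],
                   c("V113A", "Q116A", "P117A"))
  expect_identical(snap_effects[["V112A"]], "retained")

  ## HTT 494-502 region; Thr496 and Arg500 sit outside the consensus, so
  ## the motif-integrity model calls them retained even though both impair
  ## binding experimentally (a documented model limitation)
  htt <- proteinRecord("HTT_494-502", "IITEQPRGS", offset = 494)
  htt_panel <- c("I495A", "T496A", "Q498A", "P499A", "R500A")
  htt_effects <- vapply(htt_panel, function(m)
    predictMutationEffect(htt, m)$effect, character(1))
  expect_identical(names(htt_effects)[htt_effects == "lost"],
                   c("I495A", "Q498A", "P499A"))
  expect_identical(unname(htt_effects[c("T496A", "R500A")]),
                   c("retained", "retained"))
})

test_that("relaxed mode grades terminal-proline substitutions", {
  snap <- proteinRecord("SNAP25b_111-120", "GVVASQPARV", offset = 111)
  for (m in c("P117V", "P117I"))
    expect_identical(predictMutationEffect(snap, m, relaxed = TRUE)$effect,
                     "partial", info = m)
  for (m in c("P117G", "P117S", "P117T"))
    expect_identical(predictMutationEffect(snap, m, relaxed = TRUE)$effect,
                     "lost", info = m)
  ## strict mode never grants partial
  expect_identical(predictMutationEffect(snap, "P117V")$effect, "lost")
  strict <- scanMotifs(applyMutation(snap, "P117V"))
  expect_identical(nrow(strict), 0L)
})

test_that("a record without any motif hit cannot be assessed", {
  expect_error(predictMutationEffect(proteinRecord("x", "AAAAAAAA"), "A3G"),
               "no motif hit")
})
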