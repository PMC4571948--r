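test_that("charged homopolymers are disordered, hydrophobic ones ordered", {
  pk <- builtinDisorder(proteinRecord("polyK", strrep("K", 40)))
  expect_true(all(disorderCalls(pk)))
  ## closed form: H = ( -3.9 + 4.5 ) / 9, R = 1
  expect_equal(unique(round(disorderScores(pk), 6)),
               round(2.785 * (0.6 / 9) - 1 - 1.151, 6))
  pi <- builtinDisorder(proteinRecord("polyI", strrep("I", 40)))
  expect_false(any(disorderCalls(pi)))
  expect_equal(unique(round(disorderScores(pi), 6)),
               round(2.785 * 1 - 1.151, 6))
  ## the built-in track equates coil with disorder
  expect_identical(coilCalls(pk), disorderCalls(pk))
  expect_error(builtinDisorder(proteinRecord("x", "AAAA"), window = 20),
               "odd")
  expect_error(builtinDisorder(proteinRecord("x", "AAAA"), window = 1),
               "odd")
})

test_that("windowed scores equal a direct recomputation on random sequences", {
  set.seed(77)
  for (i in 1:20) {
    s <- randomSeq(80)
    res <- strsplit(s, "")[[1]]
    for (w in c(9L, 21L)) {
      track <- builtinDisorder(proteinRecord("r", s), w)
      direct <- vapply(seq_along(res), oracleDisorderScore, numeric(1),
                       res = res, window = w)
      expect_equal(disorderScores(track), direct)
      expect_identical(disorderCalls(track), direct < 0)
    }
  }
})

test_that("disorder calls are translation invariant away from the termini", {
  set.seed(78)
  s <- randomSeq(60)
  k <- 30L
  pre <- randomSeq(k)
  t1 <- builtinDisorder(proteinRecord("a", s), 21L)
  t2 <- builtinDisorder(proteinRecord("b", paste0(pre, s)), 21L)
  ## positions of s beyond the first window are unaffected by the prefix
  inner <- 11:60
  expect_equal(disorderScores(t2)[k + inner], disorderScores(t1)[inner])
})

test_that("external tracks round-trip and are validated against the record", {
  rec <- proteinRecord("p1", "GVVASQPARVKKDDEE")
  track <- builtinDisorder(rec, 5L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDisorderTrack(track, rec, path)
  back <- readDisorderTrack(path, rec, source = "roundtrip")
  expect_equal(disorderScores(back), disorderScores(track))
  expect_identical(disorderCalls(back), disorderCalls(track))
  expect_identical(back@source, "external:roundtrip")
  ## one residue short
  tab <- utils::read.delim(path, comment.char = "#")
  utils::write.table(tab[-nrow(tab), ], path, sep = "\t", row.names = FALSE)
  expect_error(readDisorderTrack(path, rec), "rows")
  ## residue mismatch names the offending position
  tab2 <- tab
  tab2$residue[7] <- "W"
  utils::write.table(tab2, path, sep = "\t", row.names = FALSE)
  expect_error(readDisorderTrack(path, rec), "position 7")
})

test_that("the two-track rescue logic follows the published rule", {
  hit <- data.frame(start = 3L, end = 8L)
  mk <- function(calls, coil = logical(0))
    new("DisorderTrack", proteinId = "p", source = "external:test",
        scores = as.numeric(calls), calls = calls, coilCalls = coil)
  n <- 12L
  all_dis <- mk(rep(TRUE, n))
  none <- mk(rep(FALSE, n), coil = rep(FALSE, n))
  coil_ord <- mk(rep(FALSE, n), coil = rep(TRUE, n))
  sec_dis <- mk(rep(TRUE, n))
  sec_ord <- mk(rep(FALSE, n))
  expect_true(motifDisordered(hit, all_dis))
  ## coil-but-ordered in the primary is rescued by a disordered secondary
  expect_true(motifDisordered(hit, coil_ord, sec_dis))
  expect_false(motifDisordered(hit, coil_ord, sec_ord))
  expect_false(motifDisordered(hit, coil_ord))          # no secondary track
  ## ordered and non-coil: secondary is never consulted
  expect_false(motifDisordered(hit, none, sec_dis))
  expect_error(motifDisordered(data.frame(start = 10L, end = 15L), all_dis),
               "not covered")
  ## majority rule
  part <- mk(c(rep(TRUE, 7), rep(FALSE, 5)))
  expect_false(motifDisordered(hit, part))              # 5/6 disordered
  expect_true(motifDisordered(hit, part, rule = "majority"))
})

test_that("the filter is monotone in the primary disorder calls", {
  set.seed(99)
  hit <- data.frame(start = 4L, end = 9L)
  for (i in 1:30) {
    calls <- sample(c(TRUE, FALSE), 15, replace = TRUE)
    tr <- new("DisorderTrack", proteinId = "p", source = "external:test",
              scores = as.numeric(calls), calls = calls,
              coilCalls = logical(0))
    before <- motifDisordered(hit, tr)
    flip <- sample(4:9, 1)
    calls2 <- calls
    calls2[flip] <- TRUE
    tr2 <- new("DisorderTrack", proteinId = "p", source = "external:test",
               scores = as.numeric(calls2), calls = calls2,
               coilCalls = logical(0))
    expect_gte(motifDisordered(hit, tr2), before)
  }
})
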