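## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (regex instead of the window matcher; move-based
## recursion instead of the Gotoh kernel).

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomSeq <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

## Start positions of general-consensus windows, by overlapping regex.
oracleGeneralStarts <- function(seq) {
  x <- "[ACDEFGHIKLMNPQRSTVWY]"
  pat <- paste0("(?=[VIAP][VIT]", x, x, "QP)")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

## Exhaustive alignment-score oracle: recursion over all monotone move
## sequences, scoring each affine gap run as open + ext * length. `memo`
## trades nothing for speed: the recursion still covers every alignment.
oracleAlignScore <- function(a, b, open = 10, ext = 0.5, memo = TRUE) {
  B <- blosum62()
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  na <- length(ra); nb <- length(rb)
  cache <- if (memo) new.env(parent = emptyenv()) else NULL
  rec <- function(i, j, prev) {
    if (i == na && j == nb) return(0)
    key <- paste(i, j, prev)
    if (memo && !is.null(cache[[key]])) return(cache[[key]])
    best <- -Inf
    if (i < na && j < nb)
      best <- max(best, B[ra[i + 1], rb[j + 1]] + rec(i + 1, j + 1, "M"))
    if (i < na)
      best <- max(best,
                  -(ext + (if (prev == "U") 0 else open)) + rec(i + 1, j, "U"))
    if (j < nb)
      best <- max(best,
                  -(ext + (if (prev == "L") 0 else open)) + rec(i, j + 1, "L"))
    if (memo) cache[[key]] <- best
    best
  }
  rec(0L, 0L, "M")
}

## Direct recomputation of the windowed fold-index score for one residue.
oracleDisorderScore <- function(res, i, window) {
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
          H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
          P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
          W = -0.9, Y = -1.3)
  chg <- c(K = 1, R = 1, D = -1, E = -1)
  h <- (window - 1) %/% 2
  idx <- max(1, i - h):min(length(res), i + h)
  H <- (mean(kd[res[idx]]) + 4.5) / 9
  R <- abs(mean(ifelse(res[idx] %in% names(chg), chg[res[idx]], 0)))
  2.785 * H - R - 1.151
}

fixturePath <- function(f) system.file("extdata", f, package = "ARBmotif")
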