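## Kyte-Doolittle hydropathy values for the 20 standard residues.
KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                   H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                   P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
                   W = -0.9, Y = -1.3)

## Formal charge at neutral pH used by the fold index: K, R = +1; D, E = -1.
AA_CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

#' Built-in windowed disorder stand-in (fold-index style)
#'
#' A self-contained per-residue disorder score in the FoldIndex family,
#' intended as a desk-testable stand-in where no external predictor track
#' is available. Over a window centred on each residue (clamped at the
#' termini), compute H = mean Kyte-Doolittle hydropathy rescaled to [0, 1]
#' by (kd + 4.5)/9 and R = |mean formal charge| (K, R = +1; D, E = -1);
#' the score is I = 2.785 H - R - 1.151 and a residue is called disordered
#' iff I < 0. The track's coil calls equal its disorder calls (the built-in
#' model carries no secondary-structure component); externally produced
#' tracks may supply real coil calls instead.
#'
#' @param record a \linkS4class{ProteinRecord}.
#' @param window odd window width >= 3 (default 21).
#' @return a \linkS4class{DisorderTrack}.
#' @examples
#' builtinDisorder(proteinRecord("polyK", strrep("K", 30)))
#' @export
builtinDisorder <- function(record, window = 21L) {
  stopifnot(is(record, "ProteinRecord"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  res <- strsplit(proteinSeq(record), "")[[1]]
  kd <- KD_HYDROPATHY[res]
  kd[is.na(kd)] <- 0          # non-standard letters contribute neutrally
  chg <- AA_CHARGE[res]
  chg[is.na(chg)] <- 0
  n <- length(res)
  h <- (window - 1L) %/% 2L
  csk <- c(0, cumsum(kd))
  csc <- c(0, cumsum(chg))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  w <- hi - lo + 1L
  H <- ((csk[hi + 1L] - csk[lo]) / w + 4.5) / 9
  R <- abs((csc[hi + 1L] - csc[lo]) / w)
  score <- unname(2.785 * H - R - 1.151)
  new("DisorderTrack", proteinId = proteinId(record), source = "builtin",
      scores = score, calls = score < 0, coilCalls = score < 0)
}

#' Read an external per-residue disorder track
#'
#' Reads a TSV with columns \code{position}, \code{residue}, \code{score},
#' \code{call} and optionally \code{coil} (lines starting with \code{#} are
#' ignored), cross-checking length and residues against the record.
#'
#' @param path TSV file.
#' @param record the \linkS4class{ProteinRecord} the track describes.
#' @param source track label, stored as \code{"external:<source>"}.
#' @return a \linkS4class{DisorderTrack}.
#' @export
readDisorderTrack <- function(path, record, source = "track") {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("position", "residue", "score", "call")
  if (!all(need %in% names(tab)))
    stop("disorder track must have columns: ", paste(need, collapse = ", "))
  res <- strsplit(proteinSeq(record), "")[[1]]
  if (nrow(tab) != length(res))
    stop("disorder track for ", proteinId(record), " has ", nrow(tab),
         " rows but the sequence has ", length(res), " residues")
  tab <- tab[order(tab$position), , drop = FALSE]
  bad <- which(toupper(tab$residue) != res)
  if (length(bad))
    stop("disorder track residue mismatch at position ",
         tab$position[bad[1]], ": track has ", tab$residue[bad[1]],
         ", sequence has ", res[bad[1]])
  coil <- if ("coil" %in% names(tab)) as.logical(tab$coil) else logical(0)
  new("DisorderTrack", proteinId = proteinId(record),
      source = paste0("external:", source),
      scores = as.numeric(tab$score), calls = as.logical(tab$call),
      coilCalls = coil)
}

#' Write a disorder track to TSV
#'
#' @param track a \linkS4class{DisorderTrack}.
#' @param record the corresponding \linkS4class{ProteinRecord}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeDisorderTrack <- function(track, record, path) {
  res <- strsplit(proteinSeq(record), "")[[1]]
  tab <- data.frame(position = seq_along(res), residue = res,
                    score = track@scores, call = track@calls)
  if (length(track@coilCalls)) tab$coil <- track@coilCalls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ARBmotif disorder track v1",
               paste0("# protein_id=", track@proteinId,
                      " source=", track@source)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Motif-level disorder filter with two-predictor rescue
#'
#' A motif hit passes the disorder filter iff all six hit residues are
#' called disordered in the primary track, OR all six are called coil (no
#' secondary structure) in the primary track while all six are called
#' disordered in the secondary track. The rescue branch mirrors running a
#' second disorder predictor on motifs that the first places in coils
#' without calling them disordered.
#'
#' @param hit single-row hit data.frame (needs \code{start}, \code{end}).
#' @param primary primary \linkS4class{DisorderTrack}.
#' @param secondary optional secondary \linkS4class{DisorderTrack}.
#' @param offset numbering offset of the protein the tracks index (default
#'   1); track positions are 1-based on the sequence.
#' @param rule \code{"all"} (every hit residue must be disordered, the
#'   default strict reading) or \code{"majority"} (> half).
#' @return logical.
#' @export
motifDisordered <- function(hit, primary, secondary = NULL, offset = 1L,
                            rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (is.data.frame(hit)) {
    if (nrow(hit) != 1L) stop("hit must be a single row")
    hit <- as.list(hit)
  }
  idx <- (hit$start:hit$end) - offset + 1L
  if (min(idx) < 1L || max(idx) > length(primary@calls))
    stop("hit span not covered by the primary disorder track")
  pass <- function(x) if (rule == "all") all(x) else mean(x) > 0.5
  if (pass(primary@calls[idx])) return(TRUE)
  if (length(primary@coilCalls) && pass(primary@coilCalls[idx]) &&
      !is.null(secondary)) {
    if (max(idx) > length(secondary@calls))
      stop("hit span not covered by the secondary disorder track")
    return(pass(secondary@calls[idx]))
  }
  FALSE
}
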