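## BLOSUM62 is loaded once from Biostrings and cached.
.pkg_cache <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' @return the 20x20 standard-residue block of BLOSUM62.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62[AA20, AA20]
  }
  .pkg_cache$blosum62
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under BLOSUM62 with affine gap penalties; a gap
#' of length L costs \code{gapOpening + gapExtension * L}. Traceback is
#' deterministic: ties prefer the diagonal, then the vertical (gap in
#' \code{b}), then the horizontal move, so identical inputs always yield the
#' identical alignment.
#'
#' @param a,b residue texts (non-empty). Non-standard letters are an error.
#' @param gapOpening,gapExtension affine gap parameters (defaults 10 and
#'   0.5, the CLUSTALW-like protein defaults).
#' @param substitutionMatrix square score matrix with residue dimnames;
#'   default BLOSUM62.
#' @return a \linkS4class{PairwiseAlignment}.
#' @examples
#' al <- nwAlign("GVVASQPARV", "GVVQPARV")
#' alignmentScore(al)
#' @export
nwAlign <- function(a, b, gapOpening = 10, gapExtension = 0.5,
                    substitutionMatrix = blosum62()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  alpha <- rownames(substitutionMatrix)
  ia <- match(strsplit(toupper(a), "")[[1]], alpha)
  ib <- match(strsplit(toupper(b), "")[[1]], alpha)
  if (anyNA(ia) || anyNA(ib))
    stop("sequences contain letters absent from the substitution matrix")
  res <- .gotoh_align(ia, ib, substitutionMatrix, gapOpening, gapExtension)
  gapped <- function(idx) {
    ch <- rep("-", length(idx))
    ch[idx > 0L] <- alpha[idx[idx > 0L]]
    paste(ch, collapse = "")
  }
  new("PairwiseAlignment", alignedA = gapped(res$a), alignedB = gapped(res$b),
      score = res$score)
}

#' Map ungapped positions of sequence A to alignment columns
#'
#' @param x a \linkS4class{PairwiseAlignment}.
#' @return integer vector: element i is the alignment column holding the
#'   i-th residue of the ungapped \code{a} input.
#' @export
columnMap <- function(x) {
  stopifnot(is(x, "PairwiseAlignment"))
  chars <- strsplit(alignedA(x), "")[[1]]
  which(chars != "-")
}

#' Create an OrthologSet
#'
#' @param reference the reference (human) \linkS4class{ProteinRecord}.
#' @param orthologs named list of \linkS4class{ProteinRecord}, keyed by
#'   species.
#' @return an \linkS4class{OrthologSet}.
#' @export
orthologSet <- function(reference, orthologs) {
  new("OrthologSet", reference = reference, orthologs = orthologs)
}

#' Classify cross-species conservation of a motif hit
#'
#' Aligns the reference against each ortholog (global, BLOSUM62, affine
#' gaps), maps the six hit columns through the alignment, and calls the
#' motif conserved iff every ortholog's mapped segment is gap-free and
#' itself matches the general consensus (class-level, not identity-level,
#' conservation). Each motif position is additionally categorized across
#' all sequences: \code{"absolute"} when identical, \code{"equivalent"}
#' when differing only within Val/Ile or Ser/Thr, else \code{"other"} --
#' the bold-type rule used for reporting conserved residues.
#'
#' @param set an \linkS4class{OrthologSet}.
#' @param hit a single-row hit data.frame from \code{\link{scanMotifs}} on
#'   the reference record.
#' @return list with \code{per_position} (character vector, length 6) and
#'   \code{motif_conserved} (logical).
#' @export
motifConserved <- function(set, hit) {
  stopifnot(is(set, "OrthologSet"))
  if (is.data.frame(hit)) {
    if (nrow(hit) != 1L) stop("hit must be a single row")
    hit <- as.list(hit)
  }
  ref <- set@reference
  i0 <- hit$start - numberingOffset(ref) + 1L
  i1 <- hit$end - numberingOffset(ref) + 1L
  if (i0 < 1L || i1 > nchar(proteinSeq(ref)))
    stop("hit span outside the reference sequence")
  refseg <- strsplit(substr(proteinSeq(ref), i0, i1), "")[[1]]
  segs <- list(reference = refseg)
  conserved <- TRUE
  for (sp in names(set@orthologs)) {
    al <- nwAlign(proteinSeq(ref), proteinSeq(set@orthologs[[sp]]))
    cols <- columnMap(al)[i0:i1]
    mapped <- strsplit(alignedB(al), "")[[1]][cols]
    segs[[sp]] <- mapped
    if (any(mapped == "-") ||
        !matchesWindow(generalConsensus(), paste(mapped, collapse = "")))
      conserved <- FALSE
  }
  per_position <- vapply(seq_along(refseg), function(i) {
    res <- unique(vapply(segs, `[`, character(1), i))
    if (length(res) == 1L) "absolute"
    else if (all(res %in% c("V", "I")) || all(res %in% c("S", "T"))) "equivalent"
    else "other"
  }, character(1))
  list(per_position = per_position, motif_conserved = conserved)
}

#' Per-column similarity shading of an aligned set
#'
#' For each column of a gapped multiple alignment, computes the fraction of
#' sequence pairs whose residues score positively under BLOSUM62 (pairs
#' involving a gap count as non-similar) and assigns the shading used for
#' conservation displays: \code{"black"} when all pairs are similar
#' (fraction 1), \code{"gray"} when the fraction lies in [0.6, 0.8], else
#' \code{"none"}.
#'
#' @param aligned character vector (>= 2) of equal-length gapped residue
#'   texts.
#' @return character vector of per-column categories.
#' @export
shadingCategories <- function(aligned) {
  if (length(aligned) < 2L) stop("at least two aligned sequences are required")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) stop("aligned texts must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  B <- blosum62()
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    pairs <- utils::combn(length(col), 2)
    sim <- apply(pairs, 2, function(p) {
      r1 <- col[p[1]]; r2 <- col[p[2]]
      if (r1 == "-" || r2 == "-" || !(r1 %in% AA20) || !(r2 %in% AA20)) FALSE
      else B[r1, r2] > 0
    })
    frac <- mean(sim)
    if (frac == 1) "black"
    else if (frac >= 0.6 && frac <= 0.8) "gray"
    else "none"
  }, character(1))
}
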