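#' Identity-based distance between two sequences
#'
#' Globally aligns the two sequences (BLOSUM62, affine gaps) and returns
#' 1 minus the fraction of identical aligned columns, counting every column
#' that is not a gap-gap pair in the denominator (columns with a single gap
#' count as non-identical). This is the usual percent-identity distance
#' behind average-linkage or neighbor-joining trees in alignment viewers.
#'
#' @param a,b residue texts.
#' @param ... passed to \code{\link{nwAlign}}.
#' @return numeric distance in [0, 1].
#' @export
identityDistance <- function(a, b, ...) {
  al <- nwAlign(a, b, ...)
  ra <- strsplit(alignedA(al), "")[[1]]
  rb <- strsplit(alignedB(al), "")[[1]]
  keep <- !(ra == "-" & rb == "-")   # never produced by pairwise NW, kept for safety
  1 - sum(ra[keep] == rb[keep] & ra[keep] != "-") / sum(keep)
}

#' Pairwise identity-distance matrix for a set of sequences
#'
#' @param seqs named character vector (or named list) of residue texts.
#' @param ... passed to \code{\link{nwAlign}}.
#' @return symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
distanceMatrix <- function(seqs, ...) {
  seqs <- unlist(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- identityDistance(seqs[[i]], seqs[[j]], ...)
    }
  }
  d
}

.checkDistanceMatrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (nrow(d) < 3L) stop("neighbor joining requires at least 3 taxa")
  if (any(!is.finite(d))) stop("distance matrix entries must be finite")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distances must be non-negative")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' the Q criterion, assign branch lengths, and reduce the matrix, ending in
#' an unrooted trifurcation. Ties in the Q criterion are broken by the
#' lexicographically lowest taxon-index pair, making the output
#' deterministic. Negative branch lengths, which NJ can produce on
#' non-additive matrices, are kept and reported with a warning.
#'
#' @param d symmetric distance matrix with zero diagonal (>= 3 taxa) and
#'   taxon names as dimnames.
#' @return an \code{ape} \code{phylo} object (unrooted).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' njTree(d)
#' @export
njTree <- function(d) {
  d <- .checkDistanceMatrix(d)
  labels <- rownames(d)
  ## Each active node carries its Newick subtree text (no trailing length).
  sub <- labels
  negative <- FALSE
  fmt <- function(x) formatC(x, format = "g", digits = 10)
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    ## lowest (i, j) pair among ties, i < j, i major
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        if (Q[i, j] < qmin - 1e-12) {
          qmin <- Q[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    if (bi < 0 || bj < 0) negative <- TRUE
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- paste0("(", sub[i], ":", fmt(bi), ",", sub[j], ":", fmt(bj), ")")
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], merged)
    sub <- c(sub[keep], merged)
    d <- d2
  }
  ## final trifurcation among the last three nodes
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (min(b1, b2, b3) < 0) negative <- TRUE
  if (negative)
    warning("neighbor joining produced negative branch length(s); kept as computed")
  newick <- paste0("(", sub[1], ":", fmt(b1), ",", sub[2], ":", fmt(b2),
                   ",", sub[3], ":", fmt(b3), ");")
  ape::read.tree(text = newick)
}

#' Neighbor-joining tree from sequences
#'
#' Convenience wrapper: identity distances from pairwise global alignments,
#' then \code{\link{njTree}}.
#'
#' @param seqs named character vector of residue texts (>= 3).
#' @param ... passed to \code{\link{nwAlign}}.
#' @return an \code{ape} \code{phylo} object.
#' @export
njFromSequences <- function(seqs, ...) {
  njTree(distanceMatrix(seqs, ...))
}

#' Write a tree to a Newick file
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
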