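#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ARBmotif, .registration = TRUE
NULL

## The 20 standard amino-acid one-letter codes, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' MotifDefinition: a position-class consensus pattern
#'
#' An ordered list of position classes (allowed residue sets) describing a
#' short linear motif such as the general \code{[VIAP][VIT]XXQP} consensus
#' recognized by the ankyrin repeat domain of zDHHC17/13, or one of its
#' three submotifs. An optional upstream-context class (used only by the
#' \code{Q[VI]TXXQP} submotif) constrains the residue immediately before the
#' core; the context residue is not part of the reported hit coordinates.
#'
#' @slot name single character label.
#' @slot labels character vector of per-position labels (e.g. "Psi", "beta",
#'   "X", "Q", "P").
#' @slot core list of character vectors; element i is the set of residues
#'   allowed at core position i.
#' @slot upstream character vector of residues allowed immediately upstream
#'   of the core, or \code{character(0)} when no context is required.
#' @slot relaxedTerminal residues granted "partial" status at the final core
#'   position when scanning in relaxed mode (\code{character(0)} disables).
#' @export
setClass("MotifDefinition",
         representation(name = "character",
                        labels = "character",
                        core = "list",
                        upstream = "character",
                        relaxedTerminal = "character"))

setValidity("MotifDefinition", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@core) != length(object@labels))
    msg <- c(msg, "core and labels must have equal length")
  ok <- vapply(object@core, function(s)
    length(s) > 0L && all(s %in% AA20) && !anyDuplicated(s), logical(1))
  if (!all(ok))
    msg <- c(msg, "every position class must be a non-empty subset of the 20 standard residues")
  if (length(object@upstream) && !all(object@upstream %in% AA20))
    msg <- c(msg, "upstream context class must be a subset of the 20 standard residues")
  if (length(object@relaxedTerminal) && !all(object@relaxedTerminal %in% AA20))
    msg <- c(msg, "relaxedTerminal must be a subset of the 20 standard residues")
  if (length(msg)) msg else TRUE
})

#' ProteinRecord: a protein sequence with a numbering convention
#'
#' Wraps one protein sequence together with the residue number of its first
#' position, so that motif hits can be reported in the numbering of the
#' full-length protein even when only a fragment is supplied (e.g. the
#' SNAP25b 111-120 decapeptide).
#'
#' @slot id single character identifier.
#' @slot description free-text description (may be empty).
#' @slot sequence uppercase residue text, non-empty.
#' @slot offset residue number of the first sequence position (>= 1).
#' @export
setClass("ProteinRecord",
         representation(id = "character",
                        description = "character",
                        sequence = "character",
                        offset = "integer"))

setValidity("ProteinRecord", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
    msg <- c(msg, "sequence must be a single non-empty string")
  if (length(object@offset) != 1L || is.na(object@offset) || object@offset < 1L)
    msg <- c(msg, "offset must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' PairwiseAlignment: result of global alignment of two sequences
#'
#' @slot alignedA,alignedB gapped residue texts of equal length; removing
#'   gaps recovers the input sequences.
#' @slot score alignment score in substitution-matrix units.
#' @export
setClass("PairwiseAlignment",
         representation(alignedA = "character",
                        alignedB = "character",
                        score = "numeric"))

setValidity("PairwiseAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned texts must have equal length")
  TRUE
})

#' OrthologSet: a reference protein and its orthologs
#'
#' @slot reference the reference (human) \linkS4class{ProteinRecord}.
#' @slot orthologs named list of \linkS4class{ProteinRecord}, one per species.
#' @export
setClass("OrthologSet",
         representation(reference = "ProteinRecord",
                        orthologs = "list"))

setValidity("OrthologSet", function(object) {
  if (length(object@orthologs) < 1L)
    return("at least one ortholog is required")
  if (!all(vapply(object@orthologs, is, logical(1), "ProteinRecord")))
    return("orthologs must be ProteinRecord objects")
  if (is.null(names(object@orthologs)) || any(!nzchar(names(object@orthologs))))
    return("orthologs must be named by species")
  TRUE
})

#' DisorderTrack: per-residue disorder (and optional coil) calls
#'
#' @slot proteinId protein the track belongs to.
#' @slot source "builtin" or "external:<name>".
#' @slot scores per-residue real-valued disorder scores.
#' @slot calls per-residue logical; TRUE = disordered.
#' @slot coilCalls per-residue logical; TRUE = coil (no secondary structure);
#'   may be length 0 when the source provides none.
#' @export
setClass("DisorderTrack",
         representation(proteinId = "character",
                        source = "character",
                        scores = "numeric",
                        calls = "logical",
                        coilCalls = "logical"))

setValidity("DisorderTrack", function(object) {
  msg <- character(0)
  if (length(object@scores) != length(object@calls))
    msg <- c(msg, "scores and calls must have equal length")
  if (length(object@coilCalls) &&
      length(object@coilCalls) != length(object@calls))
    msg <- c(msg, "coilCalls must be empty or match calls in length")
  if (length(msg)) msg else TRUE
})

#' PrioritizationReport: output of the staged candidate cascade
#'
#' @slot rows per-candidate data.frame (sorted by protein_id) with stage
#'   outcomes, hits and annotation flags.
#' @slot stageCounts named integer vector: motif_positive, physiology_pass,
#'   disorder_pass.
#' @slot flagCounts named integer vector of footnote-flag counts over the
#'   final set.
#' @slot finalIds protein ids of the final set (stage-3 survivors plus
#'   candidates tested experimentally).
#' @slot excluded data.frame(protein_id, reason) for candidates dropped at
#'   each stage.
#' @export
setClass("PrioritizationReport",
         representation(rows = "data.frame",
                        stageCounts = "integer",
                        flagCounts = "integer",
                        finalIds = "character",
                        excluded = "data.frame"))

#' SyntheticSpec: parameters of the seeded synthetic-data generators
#'
#' @slot seed master seed; per-generator streams are derived from it.
#' @slot nProteins number of background proteins to simulate.
#' @slot lengthRange integer pair, uniform protein-length range.
#' @slot motifDensity expected implanted motifs per protein (Poisson mean).
#' @slot submotifMix length-3 proportions over the three submotifs (sums to 1).
#' @slot orthologSubstRate per-residue substitution probability at non-motif
#'   positions of simulated orthologs.
#' @slot preserveMotif keep (TRUE) or ablate (FALSE) the motif in simulated
#'   orthologs.
#' @slot cascadeTargets optional non-increasing integer triple of target
#'   stage counts for engineered candidate tables (NA_integer_ disables).
#' @export
setClass("SyntheticSpec",
         representation(seed = "integer",
                        nProteins = "integer",
                        lengthRange = "integer",
                        motifDensity = "numeric",
                        submotifMix = "numeric",
                        orthologSubstRate = "numeric",
                        preserveMotif = "logical",
                        cascadeTargets = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (length(object@lengthRange) != 2L || object@lengthRange[1] > object@lengthRange[2] ||
      object@lengthRange[1] < 1L)
    msg <- c(msg, "lengthRange must be an increasing pair of positive integers")
  if (length(object@submotifMix) != 3L ||
      abs(sum(object@submotifMix) - 1) > 1e-8 || any(object@submotifMix < 0))
    msg <- c(msg, "submotifMix must be 3 non-negative proportions summing to 1")
  if (object@orthologSubstRate < 0 || object@orthologSubstRate > 1)
    msg <- c(msg, "orthologSubstRate must be in [0, 1]")
  if (object@motifDensity < 0)
    msg <- c(msg, "motifDensity must be non-negative")
  if (!all(is.na(object@cascadeTargets))) {
    ct <- object@cascadeTargets
    if (length(ct) != 3L || any(is.na(ct)) || any(ct < 0L) || is.unsorted(rev(ct)))
      msg <- c(msg, "cascadeTargets must be a non-increasing triple of non-negative integers")
  }
  if (length(msg)) msg else TRUE
})
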