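#' Create a ProteinRecord
#'
#' @param id protein identifier.
#' @param sequence residue text; lowercase letters are uppercased on ingest.
#' @param description optional free-text description.
#' @param offset residue number of the first sequence position (default 1);
#'   use e.g. \code{offset = 111} for a peptide covering residues 111-120 of
#'   the full-length protein.
#' @return a \linkS4class{ProteinRecord}.
#' @examples
#' proteinRecord("SNAP25b_111-120", "GVVASQPARV", offset = 111)
#' @export
proteinRecord <- function(id, sequence, description = "", offset = 1L) {
  new("ProteinRecord", id = as.character(id),
      description = as.character(description),
      sequence = toupper(as.character(sequence)),
      offset = as.integer(offset))
}

#' Scan a protein for AR-binding motif hits
#'
#' Slides a window of the motif-core length over the sequence and reports
#' every window (overlaps allowed) matching at least one supplied
#' definition. Coordinates are reported in protein numbering, i.e. shifted
#' by the record's \code{numberingOffset}. Each hit carries the general-
#' consensus flag, the labels of all matching submotifs, whether the
#' upstream-context requirement of the \code{Q[VI]TXXQP} submotif is met
#' (\code{FALSE} at the first sequence position, where no upstream residue
#' exists), and a full/partial qualifier ("partial" arises only in relaxed
#' mode, for windows whose terminal Pro is replaced by Val or Ile).
#'
#' @param record a \linkS4class{ProteinRecord} (or list thereof, scanned
#'   one by one and row-bound).
#' @param defs list of \linkS4class{MotifDefinition}; default all four
#'   bundled definitions.
#' @param relaxed logical; grant the relaxed "partial" qualifier at the
#'   terminal position (off by default: Val/Ile there only partially restore
#'   binding, so it is a qualifier, not a match).
#' @return data.frame with columns protein_id, start, end, matched, general,
#'   submotifs (comma-separated labels), context_ok, qualifier; one row per
#'   hit, sorted by ascending start.
#' @examples
#' rec <- proteinRecord("SNAP25b_111-120", "GVVASQPARV", offset = 111)
#' scanMotifs(rec)   # one hit: VVASQP at 112-117
#' @export
scanMotifs <- function(record, defs = motifDefinitions("all"),
                       relaxed = FALSE) {
  if (is.list(record) && !is(record, "ProteinRecord")) {
    out <- lapply(record, scanMotifs, defs = defs, relaxed = relaxed)
    return(do.call(rbind, out))
  }
  stopifnot(is(record, "ProteinRecord"))
  if (!length(defs)) stop("at least one motif definition is required")
  if (is(defs, "MotifDefinition")) defs <- list(defs)
  seq <- proteinSeq(record)
  n <- nchar(seq)
  k <- length(defs[[1]]@core)
  general <- generalConsensus()
  rows <- list()
  if (n >= k) {
    res <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (s in seq_len(n - k + 1L)) {
      window <- substr(seq, s, s + k - 1L)
      upstream <- if (s > 1L) res[s - 1L] else NA_character_
      status <- vapply(defs, .matchWindow, character(1),
                       window = window, upstream = upstream, relaxed = relaxed)
      if (all(status == "none")) next
      qualifier <- if (any(status == "full")) "full" else "partial"
      matched_defs <- defs[status != "none"]
      sublabels <- vapply(matched_defs, motifName, character(1))
      sublabels <- sublabels[sublabels != "general"]
      ctx_def <- Filter(function(d) length(d@upstream) > 0, defs)
      context_ok <- length(ctx_def) > 0 && any(vapply(
        ctx_def, function(d)
          !is.na(upstream) && toupper(upstream) %in% d@upstream, logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = proteinId(record),
        start = s + numberingOffset(record) - 1L,
        end = s + k - 1L + numberingOffset(record) - 1L,
        matched = window,
        general = .matchWindow(general, window, upstream,
                               relaxed = relaxed) == "full",
        submotifs = paste(sublabels, collapse = ","),
        context_ok = context_ok,
        qualifier = qualifier,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      general = logical(0), submotifs = character(0),
                      context_ok = logical(0), qualifier = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Parse a point-mutation label
#'
#' Parses labels of the form \code{"P117A"}: wild-type residue, position in
#' protein numbering, substituted residue.
#'
#' @param label mutation label text.
#' @return list with elements \code{position}, \code{wildType},
#'   \code{substituted}.
#' @examples
#' parseMutation("V112A")
#' @export
parseMutation <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", label))[[1]]
  if (length(m) != 4L)
    stop("malformed mutation label '", label,
         "': expected <wild-type letter><position><substituted letter>")
  list(position = as.integer(m[3L]), wildType = toupper(m[2L]),
       substituted = toupper(m[4L]))
}

#' Apply a point mutation to a protein record
#'
#' @param record a \linkS4class{ProteinRecord}.
#' @param mutation a mutation as returned by \code{\link{parseMutation}}, or
#'   a label string. The wild-type letter is checked against the sequence
#'   (in protein numbering) and a mismatch is an error.
#' @return the mutated \linkS4class{ProteinRecord}.
#' @export
applyMutation <- function(record, mutation) {
  if (is.character(mutation)) mutation <- parseMutation(mutation)
  idx <- mutation$position - numberingOffset(record) + 1L
  seq <- proteinSeq(record)
  if (idx < 1L || idx > nchar(seq))
    stop("position ", mutation$position, " outside record ", proteinId(record))
  wt <- substr(seq, idx, idx)
  if (wt != mutation$wildType)
    stop("wild-type mismatch at position ", mutation$position, ": sequence has ",
         wt, ", mutation label says ", mutation$wildType)
  substr(seq, idx, idx) <- mutation$substituted
  proteinRecord(proteinId(record), seq, record@description,
                numberingOffset(record))
}

#' Predict the effect of a point mutation on motif integrity
#'
#' Scans the record, applies the substitution, rescans, and compares hits at
#' the original hit spans. A span still covered by a full hit is
#' \code{"retained"}; covered only by a relaxed-qualifier hit,
#' \code{"partial"}; covered by nothing, \code{"lost"}. When several motif
#' hits exist, the most severe outcome across spans is reported. Note this
#' is a motif-integrity call only: residues outside the consensus (e.g.
#' HTT Thr496 and Arg500) can matter for binding experimentally while
#' leaving the motif intact.
#'
#' @inheritParams applyMutation
#' @param defs motif definitions used for scanning.
#' @param relaxed logical; enable the relaxed "partial" terminal qualifier.
#' @return list with elements \code{effect} ("retained", "partial" or
#'   "lost"), \code{before} and \code{after} (hit data.frames).
#' @examples
#' rec <- proteinRecord("SNAP25b_111-120", "GVVASQPARV", offset = 111)
#' predictMutationEffect(rec, "P117A")$effect           # "lost"
#' predictMutationEffect(rec, "V112A")$effect           # "retained"
#' predictMutationEffect(rec, "P117V", relaxed = TRUE)$effect  # "partial"
#' @export
predictMutationEffect <- function(record, mutation,
                                  defs = motifDefinitions("all"),
                                  relaxed = FALSE) {
  if (is.character(mutation)) mutation <- parseMutation(mutation)
  before <- scanMotifs(record, defs, relaxed = relaxed)
  full_before <- before[before$qualifier == "full", , drop = FALSE]
  if (!nrow(full_before))
    stop("record ", proteinId(record), " has no motif hit to assess")
  mutated <- applyMutation(record, mutation)
  after <- scanMotifs(mutated, defs, relaxed = relaxed)
  outcome <- vapply(seq_len(nrow(full_before)), function(i) {
    at <- after[after$start == full_before$start[i] &
                after$end == full_before$end[i], , drop = FALSE]
    if (any(at$qualifier == "full")) "retained"
    else if (any(at$qualifier == "partial")) "partial"
    else "lost"
  }, character(1))
  effect <- if (any(outcome == "lost")) "lost"
            else if (any(outcome == "partial")) "partial"
            else "retained"
  list(effect = effect, before = before, after = after)
}
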