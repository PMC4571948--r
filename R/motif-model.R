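## Position classes of the zDHHC17/13 AR-binding consensus.
## Psi = aliphatic V/I/A/P (Leu explicitly excluded); beta = C-beta-branched
## V/I/T; X = any standard residue; the Gln-Pro pair is invariant.
PSI_GENERAL  <- c("V", "I", "A", "P")
BETA_GENERAL <- c("V", "I", "T")

.motifDefinition <- function(name, core, labels, upstream = character(0),
                             relaxedTerminal = character(0)) {
  new("MotifDefinition", name = name, labels = labels, core = core,
      upstream = upstream, relaxedTerminal = relaxedTerminal)
}

#' Build the general AR-binding consensus
#'
#' Returns the six-position general consensus recognized by the ankyrin
#' repeat domain of zDHHC17/13: \code{[VIAP][VIT]XXQP}. Position 1 (Psi)
#' admits the aliphatic residues Val, Ile, Ala and Pro but not Leu;
#' position 2 (beta) admits the C-beta-branched Val, Ile and Thr; positions
#' 3-4 are unconstrained; Gln-Pro at positions 5-6 is invariant.
#'
#' @return a \linkS4class{MotifDefinition} of core length 6.
#' @examples
#' generalConsensus()
#' @export
generalConsensus <- function() {
  .motifDefinition("general",
                   core = list(PSI_GENERAL, BETA_GENERAL, AA20, AA20, "Q", "P"),
                   labels = c("Psi", "beta", "X", "X", "Q", "P"),
                   relaxedTerminal = c("V", "I"))
}

#' Build the three submotifs of the AR-binding consensus
#'
#' The general consensus splits into three mutually exclusive submotifs:
#' \code{[VIA][VI]XXQP}; \code{P[VI][VIL]XQP} (an additional non-variable
#' aliphatic residue when Pro occupies Psi); and \code{Q[VI]TXXQP} (a Gln
#' required immediately upstream when Thr occupies beta). The upstream Gln
#' of the third submotif is a context requirement, not part of the reported
#' six-residue hit core.
#'
#' @return list of three \linkS4class{MotifDefinition} objects.
#' @examples
#' submotifDefinitions()
#' @export
submotifDefinitions <- function() {
  list(
    .motifDefinition("submotif1",
                     core = list(c("V", "I", "A"), c("V", "I"), AA20, AA20, "Q", "P"),
                     labels = c("Psi", "beta", "X", "X", "Q", "P"),
                     relaxedTerminal = c("V", "I")),
    .motifDefinition("submotif2",
                     core = list("P", c("V", "I"), c("V", "I", "L"), AA20, "Q", "P"),
                     labels = c("Psi", "beta", "X1", "X", "Q", "P"),
                     relaxedTerminal = c("V", "I")),
    .motifDefinition("submotif3",
                     core = list(c("V", "I"), "T", AA20, AA20, "Q", "P"),
                     labels = c("Psi", "beta", "X", "X", "Q", "P"),
                     upstream = "Q",
                     relaxedTerminal = c("V", "I"))
  )
}

#' Select bundled motif definitions
#'
#' @param which one of "all" (general consensus plus the three submotifs),
#'   "general", or "submotifs".
#' @return list of \linkS4class{MotifDefinition} objects.
#' @export
motifDefinitions <- function(which = c("all", "general", "submotifs")) {
  which <- match.arg(which)
  switch(which,
         all = c(list(generalConsensus()), submotifDefinitions()),
         general = list(generalConsensus()),
         submotifs = submotifDefinitions())
}

## Internal single-window evaluation. Returns "full", "partial" or "none".
## Non-standard residue letters (B, Z, X, U, J, O, *) belong to no class and
## therefore never match; they raise no error. "partial" is only reachable
## when relaxed = TRUE: all positions match except the terminal one, whose
## residue falls in the definition's relaxedTerminal set.
.matchWindow <- function(def, window, upstream = NA_character_,
                         relaxed = FALSE) {
  k <- length(def@core)
  if (nchar(window) != k)
    stop("window length ", nchar(window), " does not match motif core length ", k)
  res <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (length(def@upstream)) {
    if (is.na(upstream) || !nzchar(upstream)) return("none")
    if (!(toupper(upstream) %in% def@upstream)) return("none")
  }
  ok <- vapply(seq_len(k), function(i) res[i] %in% def@core[[i]], logical(1))
  if (all(ok)) return("full")
  if (relaxed && length(def@relaxedTerminal) && all(ok[-k]) &&
      res[k] %in% def@relaxedTerminal) return("partial")
  "none"
}

#' Test a residue window against a motif definition
#'
#' @param def a \linkS4class{MotifDefinition}.
#' @param window residue text of the same length as the definition core.
#' @param upstream the residue immediately upstream of the window, required
#'   when the definition carries an upstream-context class; \code{NA} when
#'   no upstream residue exists (a window at the very start of a sequence
#'   can then never satisfy a context-requiring definition).
#' @return \code{TRUE} iff every window residue lies in its position class
#'   and any upstream-context requirement is satisfied.
#' @examples
#' matchesWindow(generalConsensus(), "IITEQP")   # TRUE
#' matchesWindow(generalConsensus(), "LVASQP")   # FALSE: Leu excluded at Psi
#' @export
matchesWindow <- function(def, window, upstream = NA_character_) {
  stopifnot(is(def, "MotifDefinition"))
  .matchWindow(def, window, upstream, relaxed = FALSE) == "full"
}

#' Write motif definitions to a plain-text config
#'
#' One block per definition: a \code{name} line, optional \code{upstream}
#' line, then one \code{pos<i> <allowed letters>} line per core position.
#' Blocks are separated by blank lines.
#'
#' @param defs list of \linkS4class{MotifDefinition}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeMotifConfig <- function(defs, path) {
  if (is(defs, "MotifDefinition")) defs <- list(defs)
  blocks <- vapply(defs, function(d) {
    lines <- c(paste("name", d@name),
               if (length(d@upstream))
                 paste("upstream", paste(d@upstream, collapse = "")),
               vapply(seq_along(d@core), function(i)
                 paste0("pos", i, " ", d@labels[i], " ",
                        paste(d@core[[i]], collapse = "")), character(1)),
               if (length(d@relaxedTerminal))
                 paste("relaxed_terminal", paste(d@relaxedTerminal, collapse = "")))
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Read motif definitions from a plain-text config
#'
#' @param path file written by \code{\link{writeMotifConfig}} (or hand-made
#'   in the same format, allowing user-defined motifs).
#' @return list of \linkS4class{MotifDefinition}.
#' @export
readMotifConfig <- function(path) {
  lines <- readLines(path)
  groups <- split(lines, cumsum(!nzchar(trimws(lines))))
  groups <- lapply(groups, function(g) g[nzchar(trimws(g))])
  groups <- Filter(length, groups)
  lapply(groups, function(g) {
    kv <- strsplit(trimws(g), "\\s+")
    keys <- vapply(kv, `[`, character(1), 1L)
    name <- kv[[match("name", keys)]][2L]
    upstream <- if ("upstream" %in% keys)
      strsplit(kv[[match("upstream", keys)]][2L], "")[[1]] else character(0)
    relaxed <- if ("relaxed_terminal" %in% keys)
      strsplit(kv[[match("relaxed_terminal", keys)]][2L], "")[[1]] else character(0)
    pos <- grep("^pos[0-9]+$", keys)
    pos <- pos[order(as.integer(sub("pos", "", keys[pos])))]
    core <- lapply(kv[pos], function(x) strsplit(x[3L], "")[[1]])
    labels <- vapply(kv[pos], `[`, character(1), 2L)
    .motifDefinition(name, core, labels, upstream, relaxed)
  })
}
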