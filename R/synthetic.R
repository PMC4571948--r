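## Evaluate expr with a temporarily seeded RNG, restoring the caller's
## RNG state afterwards so generators do not perturb user code.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derived per-generator streams from the master seed.
.derivedSeed <- function(seed, k) (as.integer(seed) + k) %% .Machine$integer.max

#' Construct a SyntheticSpec
#'
#' Parameters of the seeded synthetic-data generators. Defaults describe a
#' small proteome-like study condition: 50 proteins of 300-600 residues, an
#' expected one implanted motif per protein, submotifs in proportions
#' 0.5/0.3/0.2, and a 10 percent non-motif substitution rate for simulated
#' ortholog triples.
#'
#' @param seed master seed; each generator derives its own stream from it.
#' @param nProteins number of proteins.
#' @param lengthRange integer pair of protein lengths (uniform).
#' @param motifDensity expected implanted motifs per protein (Poisson).
#' @param submotifMix length-3 proportions over the three submotifs.
#' @param orthologSubstRate per-residue substitution probability at
#'   non-motif positions of simulated orthologs.
#' @param preserveMotif keep (TRUE) or ablate (FALSE) the motif in
#'   simulated orthologs.
#' @param cascadeTargets optional non-increasing triple of target stage
#'   counts for \code{\link{genCandidateTable}}.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(seed = 1L, nProteins = 50L,
                          lengthRange = c(300L, 600L), motifDensity = 1,
                          submotifMix = c(0.5, 0.3, 0.2),
                          orthologSubstRate = 0.1, preserveMotif = TRUE,
                          cascadeTargets = NA_integer_) {
  new("SyntheticSpec", seed = as.integer(seed),
      nProteins = as.integer(nProteins),
      lengthRange = as.integer(lengthRange),
      motifDensity = as.numeric(motifDensity),
      submotifMix = as.numeric(submotifMix),
      orthologSubstRate = as.numeric(orthologSubstRate),
      preserveMotif = isTRUE(preserveMotif),
      cascadeTargets = as.integer(cascadeTargets))
}

## Draw one valid submotif window. Returns the 6-residue core and, for the
## context-requiring submotif, the mandatory upstream Gln.
.sampleSubmotifWindow <- function(which) {
  def <- submotifDefinitions()[[which]]
  core <- vapply(def@core, function(cl) sample(cl, 1L), character(1))
  list(window = paste(core, collapse = ""),
       upstream = if (length(def@upstream)) def@upstream[1] else NA_character_,
       submotif = def@name)
}

#' Generate a synthetic proteome with implanted motifs and ground truth
#'
#' Background residues are drawn uniformly from the 20 standard letters;
#' per protein, a Poisson(\code{motifDensity}) number of motif windows is
#' implanted at non-overlapping positions, each drawn uniformly from the
#' allowed classes of a submotif chosen according to \code{submotifMix}
#' (the upstream Gln of the \code{Q[VI]TXXQP} submotif is implanted too).
#' The same seed yields byte-identical output.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with \code{records} (list of \linkS4class{ProteinRecord})
#'   and \code{truth} (data.frame of implanted hit coordinates: protein_id,
#'   start, end, submotif, window).
#' @export
genProteome <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (spec@motifDensity > 0 && spec@lengthRange[1] < 8L)
    stop("lengthRange too short to implant a motif (needs >= 8 residues)")
  .withSeed(.derivedSeed(spec@seed, 1L), {
    records <- vector("list", spec@nProteins)
    truth <- list()
    for (p in seq_len(spec@nProteins)) {
      L <- sample(spec@lengthRange[1]:spec@lengthRange[2], 1L)
      res <- sample(AA20, L, replace = TRUE)
      id <- sprintf("synth_%04d", p)
      k <- stats::rpois(1L, spec@motifDensity)
      kmax <- (L - 2L) %/% 8L
      k <- min(k, kmax)
      if (k > 0L) {
        ## rejection-sample non-overlapping core starts (>= 8 apart; start
        ## >= 2 so an upstream residue always exists)
        starts <- integer(0)
        for (try in seq_len(200L)) {
          cand <- sort(sample(2:(L - 6L), k))
          if (k == 1L || min(diff(cand)) >= 8L) { starts <- cand; break }
        }
        if (length(starts) == 0L)
          stop("could not place ", k, " motifs in a protein of length ", L)
        for (s in starts) {
          which_sub <- sample.int(3L, 1L, prob = spec@submotifMix)
          w <- .sampleSubmotifWindow(which_sub)
          res[s:(s + 5L)] <- strsplit(w$window, "")[[1]]
          if (!is.na(w$upstream)) res[s - 1L] <- w$upstream
          truth[[length(truth) + 1L]] <- data.frame(
            protein_id = id, start = s, end = s + 5L,
            submotif = w$submotif, window = w$window,
            stringsAsFactors = FALSE)
        }
      }
      records[[p]] <- proteinRecord(id, paste(res, collapse = ""),
                                    description = paste0("synthetic seed=",
                                                         spec@seed))
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(protein_id = character(0), start = integer(0),
                 end = integer(0), submotif = character(0),
                 window = character(0), stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Generate decoy windows violating exactly one motif position
#'
#' Each decoy starts from a valid general-consensus window and replaces the
#' residue at one constrained position (Psi, beta, Gln or Pro) with a
#' residue outside that position's class, then embeds it in inert Gly
#' flanks. By construction no decoy record contains any general-consensus
#' hit, which probes each position class independently (e.g. the Leu
#' exclusion at Psi).
#'
#' @param n number of decoys (>= 1).
#' @param seed integer seed.
#' @return list with \code{records} and \code{truth} (data.frame:
#'   protein_id, violated_position, original_window, decoy_window).
#' @export
genDecoys <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  gen <- generalConsensus()
  .withSeed(.derivedSeed(seed, 2L), {
    records <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      core <- vapply(gen@core, function(cl) sample(cl, 1L), character(1))
      pos <- sample(c(1L, 2L, 5L, 6L), 1L)
      bad <- sample(setdiff(AA20, gen@core[[pos]]), 1L)
      decoy <- core
      decoy[pos] <- bad
      id <- sprintf("decoy_%04d", i)
      records[[i]] <- proteinRecord(
        id, paste0("GG", paste(decoy, collapse = ""), "GG"),
        description = paste0("decoy violating position ", pos))
      truth[[i]] <- data.frame(
        protein_id = id, violated_position = pos,
        original_window = paste(core, collapse = ""),
        decoy_window = paste(decoy, collapse = ""),
        stringsAsFactors = FALSE)
    }
    list(records = records, truth = do.call(rbind, truth))
  })
}

#' Generate a simulated ortholog triple for a motif-bearing protein
#'
#' Emulates a human/frog/zebrafish comparison: two derived sequences are
#' produced from the reference by substituting non-motif positions
#' independently at \code{orthologSubstRate}; the motif positions of the
#' first reference hit (plus its upstream context Gln, when required) are
#' preserved when \code{preserveMotif} is TRUE, or ablated by replacing the
#' invariant Gln with Gly otherwise.
#'
#' @param record a motif-bearing \linkS4class{ProteinRecord}.
#' @param spec a \linkS4class{SyntheticSpec} (fields orthologSubstRate,
#'   preserveMotif, seed).
#' @return list with \code{set} (an \linkS4class{OrthologSet}), \code{hit}
#'   (the reference hit used) and \code{truth} (list with
#'   \code{preserved}).
#' @export
genOrthologTriple <- function(record, spec) {
  stopifnot(is(record, "ProteinRecord"), is(spec, "SyntheticSpec"))
  hits <- scanMotifs(record)
  hits <- hits[hits$qualifier == "full", , drop = FALSE]
  if (!nrow(hits)) stop("record has no motif hit; cannot build an ortholog set")
  hit <- hits[1L, , drop = FALSE]
  i0 <- hit$start - numberingOffset(record) + 1L
  protect <- i0:(i0 + 5L)
  if (hit$context_ok && i0 > 1L) protect <- c(i0 - 1L, protect)
  res <- strsplit(proteinSeq(record), "")[[1]]
  .withSeed(.derivedSeed(spec@seed, 3L), {
    orth <- lapply(c(frog_like = "frog_like",
                     zebrafish_like = "zebrafish_like"), function(sp) {
      r2 <- res
      for (i in setdiff(seq_along(r2), protect)) {
        if (stats::runif(1) < spec@orthologSubstRate)
          r2[i] <- sample(setdiff(AA20, r2[i]), 1L)
      }
      if (!spec@preserveMotif) r2[i0 + 4L] <- "G"   # ablate the invariant Gln
      proteinRecord(paste0(proteinId(record), "_", sp),
                    paste(r2, collapse = ""),
                    description = paste0("synthetic ortholog seed=", spec@seed))
    })
    list(set = orthologSet(record, orth), hit = hit,
         truth = list(preserved = spec@preserveMotif))
  })
}

#' Generate an engineered candidate table with known cascade outcome
#'
#' Builds a candidate annotation table whose flags and disorder calls are
#' set so that \code{\link{runCascade}} yields exactly the stage counts in
#' \code{spec@cascadeTargets = c(a, b, c)}: \code{a} candidates carry a
#' submotif region, of which \code{b} carry physiological evidence, of
#' which \code{c} have their motif in a disordered region. Additional
#' motif-less rows (\code{nNonMotif}) can model the wider search universe
#' dropped at stage 1.
#'
#' @param spec a \linkS4class{SyntheticSpec} with non-missing
#'   \code{cascadeTargets}.
#' @param nNonMotif number of extra candidates without any motif.
#' @return list with \code{candidates} (data.frame) and \code{expected}
#'   (list: stage counts and final-set size).
#' @export
genCandidateTable <- function(spec, nNonMotif = 0L) {
  stopifnot(is(spec, "SyntheticSpec"))
  ct <- spec@cascadeTargets
  if (any(is.na(ct)))
    stop("spec@cascadeTargets must be set for genCandidateTable")
  a <- ct[1]; b <- ct[2]; cc <- ct[3]
  .withSeed(.derivedSeed(spec@seed, 4L), {
    n <- a + nNonMotif
    region <- character(n)
    if (a > 0L) {
      for (i in seq_len(a)) {
        w <- .sampleSubmotifWindow(sample.int(3L, 1L, prob = spec@submotifMix))
        up <- if (!is.na(w$upstream)) w$upstream else "G"
        region[i] <- paste0("G", up, w$window, "GG")
      }
    }
    if (nNonMotif > 0L)
      region[a + seq_len(nNonMotif)] <- strrep("G", 10L)
    tab <- data.frame(
      protein_id = sprintf("cand_%04d", seq_len(n)),
      sequence = character(n),
      region = region,
      s_acylated = logical(n),
      dhhc17_substrate = logical(n),
      dhhc13_interactor = logical(n),
      golgi_or_pm_localized = c(rep(TRUE, b), rep(FALSE, a - b),
                                rep(TRUE, nNonMotif)),
      homolog_of_qualified = logical(n),
      motif_conserved_hfz = logical(n),
      tested_in_this_study = logical(n),
      disordered = c(rep(TRUE, cc), rep(FALSE, a - cc),
                     rep(FALSE, nNonMotif)),
      stringsAsFactors = FALSE)
    list(candidates = tab,
         expected = list(stage_counts = c(motif_positive = a,
                                          physiology_pass = b,
                                          disorder_pass = cc),
                         final_size = cc))
  })
}
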