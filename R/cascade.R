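CANDIDATE_FLAGS <- c("s_acylated", "dhhc17_substrate", "dhhc13_interactor",
                     "golgi_or_pm_localized", "homolog_of_qualified",
                     "motif_conserved_hfz", "tested_in_this_study")

## Physiological-plausibility evidence: any of these supports the ability to
## meet zDHHC17 under physiological conditions.
STAGE2_FLAGS <- c("golgi_or_pm_localized", "s_acylated", "dhhc13_interactor",
                  "homolog_of_qualified")

#' Read a candidate annotation table
#'
#' Reads a TSV with columns \code{protein_id}, \code{sequence} and/or
#' \code{region} (the printed motif-containing segment), the seven evidence
#' flags (\code{s_acylated}, \code{dhhc17_substrate},
#' \code{dhhc13_interactor}, \code{golgi_or_pm_localized},
#' \code{homolog_of_qualified}, \code{motif_conserved_hfz},
#' \code{tested_in_this_study}) and optionally \code{disordered} (an
#' externally produced motif-level disorder call). Absent flag columns are
#' filled with FALSE and a warning; lines starting with \code{#} are
#' ignored.
#'
#' @param path TSV file.
#' @return data.frame of candidates.
#' @export
readCandidateTable <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(tab))
    stop("candidate table must have a protein_id column")
  for (col in c("sequence", "region")) {
    if (!col %in% names(tab)) tab[[col]] <- ""
    tab[[col]] <- as.character(tab[[col]])   # an all-empty column reads as NA logical
  }
  missing_flags <- setdiff(CANDIDATE_FLAGS, names(tab))
  if (length(missing_flags)) {
    warning("flag column(s) absent, defaulting to FALSE: ",
            paste(missing_flags, collapse = ", "))
    for (col in missing_flags) tab[[col]] <- FALSE
  }
  for (col in CANDIDATE_FLAGS) {
    tab[[col]] <- as.logical(tab[[col]])
    tab[[col]][is.na(tab[[col]])] <- FALSE
  }
  if ("disordered" %in% names(tab)) tab$disordered <- as.logical(tab$disordered)
  tab$sequence[is.na(tab$sequence)] <- ""
  tab$region[is.na(tab$region)] <- ""
  tab
}

## Resolve the scannable record for one candidate row: a full sequence when
## present, otherwise the printed motif-region segment.
.candidateRecord <- function(row) {
  if (nzchar(row$sequence))
    list(record = proteinRecord(row$protein_id, row$sequence),
         provenance = "sequence")
  else if (nzchar(row$region))
    list(record = proteinRecord(row$protein_id, row$region),
         provenance = "region")
  else
    stop("candidate '", row$protein_id,
         "' has neither a sequence nor a motif region")
}

#' Run the staged candidate-prioritization cascade
#'
#' Stage 1 keeps candidates with at least one submotif hit in their sequence
#' or printed motif region. Stage 2 keeps those with evidence of meeting
#' zDHHC17 under physiological conditions: any of Golgi/plasma-membrane
#' localization, S-acylation, zDHHC13 interaction, or homology to a protein
#' with these features. Stage 3 keeps those whose motif is predicted to lie
#' in an intrinsically disordered region. The final set is the stage-3
#' survivors united with candidates flagged as experimentally tested in the
#' study (which enter by experiment, not by the cascade). Footnote-flag
#' counts are computed over the final set only.
#'
#' The disorder call per candidate uses, in order of precedence: the
#' table's \code{disordered} column when non-missing; a supplied disorder
#' track; otherwise the built-in windowed fold-index stand-in computed from
#' the candidate's sequence or region.
#'
#' @param candidates data.frame as from \code{\link{readCandidateTable}}.
#' @param defs motif definitions for stage 1 (default: the three submotifs).
#' @param tracks optional named list (by protein_id); each element either a
#'   \linkS4class{DisorderTrack} or a list with elements \code{primary} and
#'   \code{secondary}.
#' @param disorderWindow window width for the built-in disorder stand-in.
#' @param disorderRule \code{"all"} or \code{"majority"}, see
#'   \code{\link{motifDisordered}}.
#' @return a \linkS4class{PrioritizationReport}.
#' @export
runCascade <- function(candidates, defs = motifDefinitions("submotifs"),
                       tracks = NULL, disorderWindow = 21L,
                       disorderRule = "all") {
  stopifnot(is.data.frame(candidates))
  candidates <- candidates[order(candidates$protein_id), , drop = FALSE]
  n <- nrow(candidates)
  rows <- vector("list", n)
  excluded <- list()
  for (i in seq_len(n)) {
    row <- as.list(candidates[i, , drop = FALSE])
    cr <- .candidateRecord(row)
    hits <- scanMotifs(cr$record, defs)
    hits <- hits[hits$qualifier == "full" & nzchar(hits$submotifs), ,
                 drop = FALSE]
    stage1 <- nrow(hits) > 0L
    stage2 <- stage1 && any(unlist(row[STAGE2_FLAGS]))
    stage3 <- FALSE
    if (stage2) {
      if (!is.null(row$disordered) && !is.na(row$disordered)) {
        stage3 <- isTRUE(row$disordered)
      } else if (!is.null(tracks) && row$protein_id %in% names(tracks)) {
        tr <- tracks[[row$protein_id]]
        primary <- if (is(tr, "DisorderTrack")) tr else tr$primary
        secondary <- if (is(tr, "DisorderTrack")) NULL else tr$secondary
        stage3 <- any(vapply(seq_len(nrow(hits)), function(j)
          motifDisordered(hits[j, ], primary, secondary, rule = disorderRule),
          logical(1)))
      } else {
        primary <- builtinDisorder(cr$record, disorderWindow)
        stage3 <- any(vapply(seq_len(nrow(hits)), function(j)
          motifDisordered(hits[j, ], primary, rule = disorderRule),
          logical(1)))
      }
    }
    tested <- isTRUE(row$tested_in_this_study)
    if (!stage1)
      excluded[[length(excluded) + 1L]] <-
        data.frame(protein_id = row$protein_id, reason = "no submotif hit")
    else if (!stage2)
      excluded[[length(excluded) + 1L]] <-
        data.frame(protein_id = row$protein_id,
                   reason = "no physiological evidence")
    else if (!stage3)
      excluded[[length(excluded) + 1L]] <-
        data.frame(protein_id = row$protein_id,
                   reason = "motif not in a disordered region")
    rows[[i]] <- data.frame(
      protein_id = row$protein_id,
      provenance = cr$provenance,
      n_hits = nrow(hits),
      submotifs = paste(unique(unlist(strsplit(hits$submotifs, ","))),
                        collapse = ","),
      stage1_motif = stage1, stage2_physiology = stage2,
      stage3_disorder = stage3,
      in_final_set = stage3 || tested,
      s_acylated = isTRUE(row$s_acylated),
      dhhc17_substrate = isTRUE(row$dhhc17_substrate),
      dhhc13_interactor = isTRUE(row$dhhc13_interactor),
      golgi_or_pm_localized = isTRUE(row$golgi_or_pm_localized),
      homolog_of_qualified = isTRUE(row$homolog_of_qualified),
      motif_conserved_hfz = isTRUE(row$motif_conserved_hfz),
      tested_in_this_study = tested,
      stringsAsFactors = FALSE)
  }
  rows <- if (n) do.call(rbind, rows) else
    data.frame(protein_id = character(0), provenance = character(0),
               n_hits = integer(0), submotifs = character(0),
               stage1_motif = logical(0), stage2_physiology = logical(0),
               stage3_disorder = logical(0), in_final_set = logical(0))
  final <- rows$protein_id[rows$in_final_set]
  fin <- rows[rows$in_final_set, , drop = FALSE]
  flagCounts <- c(
    s_acylated = sum(fin$s_acylated),
    dhhc17_substrate = sum(fin$dhhc17_substrate),
    dhhc13_interactor = sum(fin$dhhc13_interactor),
    motif_conserved_hfz = sum(fin$motif_conserved_hfz))
  new("PrioritizationReport",
      rows = rows,
      stageCounts = c(motif_positive = sum(rows$stage1_motif),
                      physiology_pass = sum(rows$stage2_physiology),
                      disorder_pass = sum(rows$stage3_disorder)),
      flagCounts = as.integer(flagCounts) |> stats::setNames(names(flagCounts)),
      finalIds = final,
      excluded = if (length(excluded)) do.call(rbind, excluded) else
        data.frame(protein_id = character(0), reason = character(0)))
}

#' Write a prioritization report to TSV
#'
#' Writes the per-candidate rows preceded by a commented header naming the
#' schema and the summary counts.
#'
#' @param report a \linkS4class{PrioritizationReport}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(report, path) {
  sc <- stageCounts(report)
  fc <- flagCounts(report)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ARBmotif prioritization report v1",
    paste0("# stage_counts motif_positive=", sc[["motif_positive"]],
           " physiology_pass=", sc[["physiology_pass"]],
           " disorder_pass=", sc[["disorder_pass"]]),
    paste0("# final_set_size=", length(finalSet(report))),
    paste0("# flag_counts s_acylated=", fc[["s_acylated"]],
           " dhhc17_substrate=", fc[["dhhc17_substrate"]],
           " dhhc13_interactor=", fc[["dhhc13_interactor"]],
           " motif_conserved_hfz=", fc[["motif_conserved_hfz"]])), con)
  utils::write.table(reportRows(report), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
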