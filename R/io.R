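#' Read protein records from a FASTA file
#'
#' Standard multi-record FASTA via Biostrings (wrapped lines joined, CRLF
#' tolerated). Record ids are the first whitespace-delimited token of the
#' header; the remainder becomes the description. Sequences are uppercased;
#' non-standard letters are kept but reported via a message (they never
#' match any motif position class).
#'
#' @param path FASTA file.
#' @param offset numbering offset applied to every record (default 1).
#' @return list of \linkS4class{ProteinRecord}.
#' @export
readFastaRecords <- function(path, offset = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readBStringSet(path)
  if (!length(aa)) stop("FASTA file contains no records: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("\r", "", as.character(aa)))
  if (any(!nzchar(seqs)))
    stop("record with empty sequence: ", ids[!nzchar(seqs)][1])
  odd <- vapply(seqs, function(s)
    any(!strsplit(s, "")[[1]] %in% AA20), logical(1))
  if (any(odd))
    message("note: non-standard residue letters in ",
            paste(ids[odd], collapse = ", "),
            " (they match no motif position class)")
  mapply(function(id, d, s) proteinRecord(id, s, d, offset),
         ids, descs, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records list of \linkS4class{ProteinRecord}.
#' @param path output file.
#' @param width line-wrap width.
#' @return invisibly, \code{path}.
#' @export
writeFastaRecords <- function(records, path, width = 60L) {
  if (is(records, "ProteinRecord")) records <- list(records)
  seqs <- Biostrings::AAStringSet(vapply(records, proteinSeq, character(1)))
  names(seqs) <- vapply(records, function(r) {
    d <- r@description
    if (nzchar(d)) paste(proteinId(r), d) else proteinId(r)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Write motif hits to TSV
#'
#' @param hits hit data.frame from \code{\link{scanMotifs}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeHits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ARBmotif hits v1",
               "# columns: protein_id start end matched general submotifs context_ok qualifier",
               "# coordinates are 1-based inclusive in protein numbering"), con)
  utils::write.table(hits, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a candidate table to TSV
#'
#' @param candidates candidate data.frame (see
#'   \code{\link{readCandidateTable}}).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeCandidateTable <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ARBmotif candidate table v1", con)
  utils::write.table(candidates, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Flat key-value configuration governing the pipeline stages. Values given
#' in \code{...} override the defaults; \code{\link{readPipelineConfig}}
#' reads the same keys from a plain-text file, and command-line flags
#' override both (precedence: CLI > file > defaults).
#'
#' @param ... named overrides of the defaults.
#' @return validated named list with keys: motifs ("all", "general" or
#'   "submotifs"), relaxed, gap_opening, gap_extension, disorder_window,
#'   disorder_rule ("all" or "majority"), shading_gray_min,
#'   shading_gray_max, seed.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(motifs = "all", relaxed = FALSE, gap_opening = 10,
              gap_extension = 0.5, disorder_window = 21L,
              disorder_rule = "all", shading_gray_min = 0.6,
              shading_gray_max = 0.8, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$relaxed <- isTRUE(cfg$relaxed) || identical(cfg$relaxed, "true")
  cfg$disorder_window <- as.integer(cfg$disorder_window)
  cfg$seed <- as.integer(cfg$seed)
  for (k in c("gap_opening", "gap_extension", "shading_gray_min",
              "shading_gray_max"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  if (!cfg$motifs %in% c("all", "general", "submotifs"))
    stop("config: motifs must be one of all, general, submotifs")
  if (!cfg$disorder_rule %in% c("all", "majority"))
    stop("config: disorder_rule must be all or majority")
  if (cfg$disorder_window < 3L || cfg$disorder_window %% 2L == 0L)
    stop("config: disorder_window must be an odd integer >= 3")
  cfg
}

#' Read a pipeline configuration file
#'
#' Plain-text \code{key value} (or \code{key=value}) lines; \code{#} starts
#' a comment.
#'
#' @param path config file.
#' @return validated config list (see \code{\link{pipelineConfig}}).
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(sub("=", " ", lines), "\\s+")
  vals <- lapply(kv, function(x) paste(x[-1], collapse = " "))
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  do.call(pipelineConfig, vals)
}
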