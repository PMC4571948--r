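#' @rdname accessors
#' @param x an ARBmotif S4 object.
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))
#' @rdname accessors
#' @export
setGeneric("coreClasses", function(x) standardGeneric("coreClasses"))
#' @rdname accessors
#' @export
setGeneric("upstreamContext", function(x) standardGeneric("upstreamContext"))
#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))
#' @rdname accessors
#' @export
setGeneric("proteinSeq", function(x) standardGeneric("proteinSeq"))
#' @rdname accessors
#' @export
setGeneric("numberingOffset", function(x) standardGeneric("numberingOffset"))
#' @rdname accessors
#' @export
setGeneric("alignedA", function(x) standardGeneric("alignedA"))
#' @rdname accessors
#' @export
setGeneric("alignedB", function(x) standardGeneric("alignedB"))
#' @rdname accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname accessors
#' @export
setGeneric("disorderCalls", function(x) standardGeneric("disorderCalls"))
#' @rdname accessors
#' @export
setGeneric("disorderScores", function(x) standardGeneric("disorderScores"))
#' @rdname accessors
#' @export
setGeneric("coilCalls", function(x) standardGeneric("coilCalls"))
#' @rdname accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))
#' @rdname accessors
#' @export
setGeneric("flagCounts", function(x) standardGeneric("flagCounts"))
#' @rdname accessors
#' @export
setGeneric("finalSet", function(x) standardGeneric("finalSet"))
#' @rdname accessors
#' @export
setGeneric("reportRows", function(x) standardGeneric("reportRows"))

#' Accessors for ARBmotif classes
#'
#' Small read-only accessors exposing the slots of the package's S4 classes.
#'
#' @name accessors
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setMethod("motifName", "MotifDefinition", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("coreClasses", "MotifDefinition", function(x) {
  names(x@core) <- x@labels
  x@core
})
#' @rdname accessors
#' @export
setMethod("upstreamContext", "MotifDefinition", function(x) x@upstream)
#' @rdname accessors
#' @export
setMethod("proteinId", "ProteinRecord", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("proteinSeq", "ProteinRecord", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("numberingOffset", "ProteinRecord", function(x) x@offset)
#' @rdname accessors
#' @export
setMethod("alignedA", "PairwiseAlignment", function(x) x@alignedA)
#' @rdname accessors
#' @export
setMethod("alignedB", "PairwiseAlignment", function(x) x@alignedB)
#' @rdname accessors
#' @export
setMethod("alignmentScore", "PairwiseAlignment", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("disorderCalls", "DisorderTrack", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("disorderScores", "DisorderTrack", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("coilCalls", "DisorderTrack", function(x) x@coilCalls)
#' @rdname accessors
#' @export
setMethod("stageCounts", "PrioritizationReport", function(x) x@stageCounts)
#' @rdname accessors
#' @export
setMethod("flagCounts", "PrioritizationReport", function(x) x@flagCounts)
#' @rdname accessors
#' @export
setMethod("finalSet", "PrioritizationReport", function(x) x@finalIds)
#' @rdname accessors
#' @export
setMethod("reportRows", "PrioritizationReport", function(x) x@rows)

setMethod("show", "MotifDefinition", function(object) {
  pat <- vapply(seq_along(object@core), function(i) {
    s <- object@core[[i]]
    if (length(s) == 1L) s
    else if (setequal(s, AA20)) "X"
    else paste0("[", paste(s, collapse = ""), "]")
  }, character(1))
  ctx <- if (length(object@upstream))
    paste0("(", paste(object@upstream, collapse = ""), ")") else ""
  cat("MotifDefinition '", object@name, "': ", ctx, paste(pat, collapse = ""),
      "\n", sep = "")
})

setMethod("show", "ProteinRecord", function(object) {
  n <- nchar(object@sequence)
  cat("ProteinRecord ", object@id, " [", object@offset, "-",
      object@offset + n - 1L, "] (", n, " aa)\n", sep = "")
})

setMethod("show", "PairwiseAlignment", function(object) {
  cat("PairwiseAlignment (score ", object@score, ")\n",
      object@alignedA, "\n", object@alignedB, "\n", sep = "")
})

setMethod("show", "DisorderTrack", function(object) {
  cat("DisorderTrack ", object@proteinId, " [", object@source, "]: ",
      sum(object@calls), "/", length(object@calls),
      " residues called disordered\n", sep = "")
})

setMethod("show", "OrthologSet", function(object) {
  cat("OrthologSet: reference ", object@reference@id, " + ",
      length(object@orthologs), " ortholog(s): ",
      paste(names(object@orthologs), collapse = ", "), "\n", sep = "")
})

setMethod("show", "PrioritizationReport", function(object) {
  sc <- object@stageCounts
  fc <- object@flagCounts
  cat("PrioritizationReport\n",
      "  stage 1 (submotif hit):      ", sc[["motif_positive"]], "\n",
      "  stage 2 (physiology filter): ", sc[["physiology_pass"]], "\n",
      "  stage 3 (disorder filter):   ", sc[["disorder_pass"]], "\n",
      "  final set (incl. tested):    ", length(object@finalIds), "\n",
      "  flags over final set: s_acylated=", fc[["s_acylated"]],
      ", dhhc17_substrate=", fc[["dhhc17_substrate"]],
      ", dhhc13_interactor=", fc[["dhhc13_interactor"]],
      ", motif_conserved_hfz=", fc[["motif_conserved_hfz"]], "\n", sep = "")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec: seed=", object@seed, ", n=", object@nProteins,
      ", length=[", object@lengthRange[1], ",", object@lengthRange[2],
      "], density=", object@motifDensity, "\n", sep = "")
})
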