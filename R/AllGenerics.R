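# Generics and simple accessor/show methods.

#' @rdname Repertoire-class
#' @param x,object a package object.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname Repertoire-class
#' @export
setMethod("sampleId", "Repertoire", function(x) x@sampleId)
#' @rdname ConvergentGroups-class
#' @export
setMethod("sampleId", "ConvergentGroups", function(x) x@sampleId)

#' @rdname Repertoire-class
#' @export
setGeneric("clonotypes", function(x) standardGeneric("clonotypes"))
#' @rdname Repertoire-class
#' @export
setMethod("clonotypes", "Repertoire", function(x) x@clonotypes)

#' @rdname Repertoire-class
#' @export
setGeneric("nClonotypes", function(x) standardGeneric("nClonotypes"))
#' @rdname Repertoire-class
#' @export
setMethod("nClonotypes", "Repertoire", function(x) nrow(x@clonotypes))

#' @rdname Repertoire-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname Repertoire-class
#' @export
setMethod("totalReads", "Repertoire", function(x) sum(x@clonotypes$count))

#' @rdname Repertoire-class
#' @export
setGeneric("isQCFiltered", function(x) standardGeneric("isQCFiltered"))
#' @rdname Repertoire-class
#' @export
setMethod("isQCFiltered", "Repertoire", function(x) x@qcFiltered)

#' @rdname Repertoire-class
#' @export
setGeneric("qcSummary", function(x) standardGeneric("qcSummary"))
#' @rdname Repertoire-class
#' @export
setMethod("qcSummary", "Repertoire", function(x) x@qcSummary)

#' @rdname ConvergentGroups-class
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))
#' @rdname ConvergentGroups-class
#' @export
setMethod("groupTable", "ConvergentGroups", function(x) x@groups)

#' @rdname Cohort-class
#' @export
setGeneric("repertoires", function(x) standardGeneric("repertoires"))
#' @rdname Cohort-class
#' @export
setMethod("repertoires", "Cohort", function(x) x@repertoires)
#' @rdname Cohort-class
#' @export
setMethod("length", "Cohort", function(x) length(x@repertoires))
#' @rdname Cohort-class
#' @param i index or sample id.
#' @param j,... unused.
#' @export
setMethod("[[", "Cohort", function(x, i, j, ...) x@repertoires[[i]])
#' @rdname Cohort-class
#' @export
setMethod("names", "Cohort", function(x) names(x@repertoires))

#' @rdname PublicSet-class
#' @param x a \code{PublicSet}.
#' @export
setGeneric("publicKeys", function(x) standardGeneric("publicKeys"))
#' @rdname PublicSet-class
#' @export
setMethod("publicKeys", "PublicSet", function(x) x@keys)

#' @rdname PairedCells-class
#' @param x a \code{PairedCells} object.
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @rdname PairedCells-class
#' @export
setMethod("cells", "PairedCells", function(x) x@cells)
#' @rdname PairedCells-class
#' @export
setGeneric("droppedCells", function(x) standardGeneric("droppedCells"))
#' @rdname PairedCells-class
#' @export
setMethod("droppedCells", "PairedCells", function(x) x@dropped)

setMethod("show", "Repertoire", function(object) {
  cat(sprintf("Repertoire '%s': %d clonotypes, %s reads%s\n",
              object@sampleId, nrow(object@clonotypes),
              format(sum(object@clonotypes$count), big.mark = ","),
              if (object@qcFiltered) " (QC-filtered)" else ""))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort of %d repertoires: %s\n", length(object@repertoires),
              paste(head(names(object@repertoires), 5), collapse = ", ")))
})

setMethod("show", "ConvergentGroups", function(object) {
  g <- object@groups
  cat(sprintf(
    "ConvergentGroups '%s' (%s): %d groups, %d convergent (degeneracy >= 2)\n",
    object@sampleId, object@mode, nrow(g), sum(g$degeneracy >= 2L)))
})

setMethod("show", "PublicSet", function(object) {
  cat(sprintf(
    "PublicSet: %d keys shared by >= %d of %d individuals (threshold %.3g)\n",
    length(object@keys), object@minIndividuals, object@nIndividuals,
    object@threshold))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: OR = %.4g (log10 %.3f)%s, p = %.4g\n",
              object@oddsRatio, object@log10OddsRatio,
              if (object@corrected) " [zero-cell corrected]" else "",
              object@pValue))
  print(object@table)
})

setMethod("show", "QCPolicy", function(object) {
  cat(sprintf("QCPolicy: length [%d, %d], start '%s', end '%s', 20-aa alphabet\n",
              object@minLen, object@maxLen, object@requiredStart,
              object@requiredEnd))
})

setMethod("show", "PairedCells", function(object) {
  cat(sprintf("PairedCells: %d cells (%d with alpha); dropped %d no-beta, %d multi-beta\n",
              nrow(object@cells), sum(!is.na(object@cells$alpha_cdr3_aa)),
              object@dropped$no_beta, object@dropped$multi_beta))
})
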