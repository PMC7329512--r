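#' Accessors for bin and matrix objects
#'
#' @param x A [BinSpec-class] or [BinMatrix-class] object.
#' @return \code{binChrom}, \code{binStart}, \code{binEnd} return the bin
#'   coordinates (0-based, half-open); \code{cpgPositions} the 0-based CpG
#'   positions; \code{binDensity} the CpG density \eqn{d}; \code{binOf} the
#'   [BinSpec-class] of a matrix; \code{callMatrix} the reads x CpGs
#'   integer matrix; \code{readLabels} the per-row library labels;
#'   \code{readIds} the per-row read identifiers.
#' @name bin-accessors
NULL

#' @rdname bin-accessors
#' @export
setGeneric("binChrom", function(x) standardGeneric("binChrom"))
#' @rdname bin-accessors
#' @export
setGeneric("binStart", function(x) standardGeneric("binStart"))
#' @rdname bin-accessors
#' @export
setGeneric("binEnd", function(x) standardGeneric("binEnd"))
#' @rdname bin-accessors
#' @export
setGeneric("cpgPositions", function(x) standardGeneric("cpgPositions"))
#' @rdname bin-accessors
#' @export
setGeneric("binDensity", function(x) standardGeneric("binDensity"))
#' @rdname bin-accessors
#' @export
setGeneric("binOf", function(x) standardGeneric("binOf"))
#' @rdname bin-accessors
#' @export
setGeneric("callMatrix", function(x) standardGeneric("callMatrix"))
#' @rdname bin-accessors
#' @export
setGeneric("readLabels", function(x) standardGeneric("readLabels"))
#' @rdname bin-accessors
#' @export
setGeneric("readIds", function(x) standardGeneric("readIds"))

#' Accessors for cluster reports
#'
#' @param x A [ClusterReport-class].
#' @return \code{clusters} returns the cluster table as a
#'   [S4Vectors::DataFrame-class]; \code{reportParams} the list of run
#'   parameters; \code{nBinsProcessed} / \code{nBinsSkipped} the bin
#'   bookkeeping counts.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname report-accessors
#' @export
setGeneric("reportParams", function(x) standardGeneric("reportParams"))
#' @rdname report-accessors
#' @export
setGeneric("nBinsProcessed", function(x) standardGeneric("nBinsProcessed"))
#' @rdname report-accessors
#' @export
setGeneric("nBinsSkipped", function(x) standardGeneric("nBinsSkipped"))

setMethod("binChrom", "BinSpec", function(x) x@chrom)
setMethod("binStart", "BinSpec", function(x) x@start)
setMethod("binEnd", "BinSpec", function(x) x@end)
setMethod("cpgPositions", "BinSpec", function(x) x@cpgPositions)
setMethod("binDensity", "BinSpec", function(x) length(x@cpgPositions))

setMethod("binChrom", "BinMatrix", function(x) x@bin@chrom)
setMethod("binStart", "BinMatrix", function(x) x@bin@start)
setMethod("binEnd", "BinMatrix", function(x) x@bin@end)
setMethod("cpgPositions", "BinMatrix", function(x) x@bin@cpgPositions)
setMethod("binDensity", "BinMatrix", function(x) length(x@bin@cpgPositions))
setMethod("binOf", "BinMatrix", function(x) x@bin)
setMethod("callMatrix", "BinMatrix", function(x) x@calls)
setMethod("readLabels", "BinMatrix", function(x) x@labels)
setMethod("readIds", "BinMatrix", function(x) x@readIds)

setMethod("clusters", "ClusterReport", function(x) x@clusters)
setMethod("reportParams", "ClusterReport", function(x) x@params)
setMethod("nBinsProcessed", "ClusterReport", function(x) x@nBinsProcessed)
setMethod("nBinsSkipped", "ClusterReport", function(x) x@nBinsSkipped)

setMethod("show", "BinSpec", function(object) {
  cat(sprintf("BinSpec %s:%d-%d (d = %d CpGs)\n", object@chrom,
              object@start, object@end, length(object@cpgPositions)))
})

setMethod("show", "BinMatrix", function(object) {
  inf <- sum(rowSums(object@calls == -1L) == 0L)
  cat(sprintf("BinMatrix %s:%d-%d | %d reads x %d CpGs | %d informative | libraries: %s\n",
              object@bin@chrom, object@bin@start, object@bin@end,
              nrow(object@calls), ncol(object@calls), inf,
              paste(unique(object@labels), collapse = ", ")))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf("ClusterReport: %d clusters in %d bins (%d bins skipped), mode = %s\n",
              nrow(object@clusters), object@nBinsProcessed,
              object@nBinsSkipped,
              if (is.null(object@params$mode)) "?" else object@params$mode))
})

setMethod("show", "ImputationModel", function(object) {
  cat(sprintf("ImputationModel (library '%s'), densities: %s\n",
              object@trainLibrary, paste(names(object@models), collapse = ", ")))
  if (nrow(object@metrics)) {
    df <- as.data.frame(object@metrics)
    print(df, row.names = FALSE)
  }
})

setMethod("show", "ProportionModel", function(object) {
  cat(sprintf("ProportionModel: %d features -> %d components, CV RMSE = %.4g\n",
              length(object@columns), object@nComponents, object@cvRMSE))
})
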