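#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom BiocGenerics start
NULL

#' BinSpec: a 100-bp genomic bin with its CpG positions
#'
#' A lightweight container for one genomic bin. Coordinates are 0-based,
#' half-open (BED convention) throughout the package; bins tile each
#' chromosome from position 0 and a final partial bin (< 100 bp) at the
#' chromosome end is retained. \code{cpgPositions} holds the 0-based
#' positions of the C of each CpG dinucleotide falling in
#' \code{[start, end)}, collapsed onto the forward strand. The number of
#' CpG positions is the bin's CpG density \eqn{d}.
#'
#' @slot chrom Chromosome (contig) name.
#' @slot start 0-based inclusive bin start.
#' @slot end Exclusive bin end; \code{end - start <= 100}.
#' @slot cpgPositions Strictly increasing integer vector of 0-based CpG
#'   C positions within \code{[start, end)}.
#'
#' @seealso [BinSpec()], [binDensity()], [enumerateBins()],
#'   [binsFromReference()]
#' @export
setClass("BinSpec",
  representation(
    chrom = "character",
    start = "integer",
    end = "integer",
    cpgPositions = "integer"
  )
)

setValidity("BinSpec", function(object) {
  msg <- NULL
  if (length(object@chrom) != 1L || length(object@start) != 1L ||
      length(object@end) != 1L)
    msg <- c(msg, "chrom, start and end must be scalars")
  else {
    if (object@end <= object@start)
      msg <- c(msg, "end must exceed start")
    if (object@end - object@start > 100L)
      msg <- c(msg, "bins are at most 100 bp")
    p <- object@cpgPositions
    if (length(p)) {
      if (any(p < object@start | p >= object@end))
        msg <- c(msg, "cpgPositions must lie in [start, end)")
      if (is.unsorted(p, strictly = TRUE))
        msg <- c(msg, "cpgPositions must be strictly increasing")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' BinMatrix: reads x CpGs call matrix for one bin
#'
#' Rows are read segments overlapping at least one CpG of the bin; columns
#' are the bin's CpG positions in genomic order. Entries are 1 (methylated),
#' 0 (unmethylated) or -1 (the read does not cover that CpG). A row with no
#' -1 is an \emph{informative} read. Each row carries the label of the
#' library (input alignment file) it came from.
#'
#' @slot bin A [BinSpec-class] object.
#' @slot calls Integer matrix over \{-1, 0, 1\} with one column per bin CpG.
#' @slot labels Character vector of per-row library labels.
#' @slot readIds Character vector of per-row read identifiers.
#'
#' @seealso [BinMatrix()], [loadBinMatrix()], [clusterReads()],
#'   [imputeMatrix()]
#' @export
setClass("BinMatrix",
  representation(
    bin = "BinSpec",
    calls = "matrix",
    labels = "character",
    readIds = "character"
  )
)

setValidity("BinMatrix", function(object) {
  msg <- NULL
  m <- object@calls
  if (ncol(m) != length(object@bin@cpgPositions))
    msg <- c(msg, "calls must have one column per bin CpG")
  if (nrow(m) != length(object@labels) || nrow(m) != length(object@readIds))
    msg <- c(msg, "labels and readIds must match the number of rows")
  if (length(m) && !all(m %in% c(-1L, 0L, 1L)))
    msg <- c(msg, "calls entries must be -1, 0 or 1")
  if (is.null(msg)) TRUE else msg
})

#' ClusterReport: genome-wide summary of read clusters
#'
#' Holds one row per retained cluster (a group of at least
#' \code{minClusterSize} informative reads sharing an identical methylation
#' pattern within a bin), annotated with genomic location, pattern,
#' per-library read counts, shared/sample-specific status, major/minor
#' class per library and per-bin informative-read totals after depth
#' equalisation. Run parameters and the number of bins skipped for
#' insufficient coverage are recorded alongside.
#'
#' @slot clusters A [S4Vectors::DataFrame-class] with columns \code{chrom},
#'   \code{bin_start}, \code{bin_end}, \code{pattern}, \code{count_A},
#'   \code{count_B}, \code{specificity}, \code{class_A}, \code{class_B},
#'   \code{bin_total_A}, \code{bin_total_B}. In single-library mode the
#'   \code{B} columns are \code{NA}.
#' @slot params Named list of run parameters (input labels, thresholds,
#'   seed, mode).
#' @slot nBinsProcessed Number of bins that passed coverage filters.
#' @slot nBinsSkipped Number of bins dropped for insufficient coverage.
#'
#' @seealso [compareLibraries()], [clusterBins()], [writeClusterReport()],
#'   [summarizeUniqueFraction()]
#' @export
setClass("ClusterReport",
  representation(
    clusters = "DataFrame",
    params = "list",
    nBinsProcessed = "integer",
    nBinsSkipped = "integer"
  )
)

setValidity("ClusterReport", function(object) {
  need <- c("chrom", "bin_start", "bin_end", "pattern", "count_A",
            "count_B", "specificity", "class_A", "class_B",
            "bin_total_A", "bin_total_B")
  if (!all(need %in% colnames(object@clusters)))
    return(paste("clusters must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' ImputationModel: per-density read-level imputation models
#'
#' One trained probability forest per CpG density \eqn{d} (by default
#' densities 2--5), each with the hyperparameters chosen by cross-validated
#' grid search and held-out performance metrics. Models emit the probability
#' of methylation \eqn{y} for a missing read-level CpG call; downstream
#' gating uses the confidence \eqn{C = |2(y - 0.5)|}.
#'
#' @slot models Named list (names = densities) of fitted ranger forests.
#' @slot chosen Named list of chosen hyperparameters per density.
#' @slot metrics [S4Vectors::DataFrame-class] with per-density held-out AUC
#'   and AUPRC.
#' @slot trainLibrary Label of the library the model was trained on.
#' @slot seed Integer seed used for the split/grid search.
#'
#' @seealso [trainImputationModel()], [imputeMatrix()], [predictMissing()]
#' @export
setClass("ImputationModel",
  representation(
    models = "list",
    chosen = "list",
    metrics = "DataFrame",
    trainLibrary = "character",
    seed = "integer"
  )
)

#' ProportionModel: cell-mixture proportion estimator
#'
#' A principal-components regression of true mixture proportions on
#' cluster-count features: features are centred, projected onto the top
#' \code{nComponents} principal components fitted on the training table,
#' and a multivariate linear regression maps components to the proportion.
#' Prediction requires feature alignment to the stored training column
#' order (see [alignFeatures()]); predictions are clipped to [0, 1].
#'
#' @slot center Numeric vector of training column means.
#' @slot rotation Loadings matrix (columns = components).
#' @slot coefficients Regression coefficients (intercept first).
#' @slot columns Training feature-column identifiers, in order.
#' @slot nComponents Number of retained components.
#' @slot cvRMSE Cross-validated root mean squared error on the training
#'   table.
#'
#' @seealso [fitProportionModel()], [predictProportions()]
#' @export
setClass("ProportionModel",
  representation(
    center = "numeric",
    rotation = "matrix",
    coefficients = "numeric",
    columns = "character",
    nComponents = "integer",
    cvRMSE = "numeric"
  )
)
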