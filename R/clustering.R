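## Run code under a local, restored RNG state when a seed is given.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  code
}

#' Identify informative rows of a bin matrix
#'
#' An informative read covers every CpG of the bin, i.e. its row contains
#' no -1.
#'
#' @param x A [BinMatrix-class].
#' @return Logical vector over rows.
#' @export
informativeRows <- function(x) {
  m <- callMatrix(x)
  if (nrow(m) == 0L) return(logical(0))
  rowSums(m == -1L) == 0L
}

#' Phase 1 coverage accounting for one bin
#'
#' Counts informative reads (rows with no missing call) and flags bins
#' with fewer than 2 CpGs as ineligible for cluster analysis.
#'
#' @param x A [BinMatrix-class].
#' @param byLibrary If TRUE, return per-library informative counts as a
#'   named vector instead of the summary row.
#' @return A one-row data.frame (\code{chrom}, \code{bin_start},
#'   \code{bin_end}, \code{n_cpgs}, \code{n_informative_reads},
#'   \code{eligible}) or a named integer vector.
#' @export
computeBinCoverage <- function(x, byLibrary = FALSE) {
  inf <- informativeRows(x)
  if (byLibrary) {
    labs <- readLabels(x)[inf]
    return(vapply(split(labs, factor(labs, levels = sort(unique(readLabels(x))))),
                  length, integer(1)))
  }
  data.frame(chrom = binChrom(x), bin_start = binStart(x),
             bin_end = binEnd(x), n_cpgs = binDensity(x),
             n_informative_reads = sum(inf),
             eligible = binDensity(x) >= 2L,
             stringsAsFactors = FALSE)
}

#' Coverage table over many bins
#'
#' @param matrices List of [BinMatrix-class] objects.
#' @param label Optional library label; if given, only reads from that
#'   library are counted (one coverage table per input library).
#' @return data.frame with one row per bin.
#' @export
coverageTable <- function(matrices, label = NULL) {
  rows <- lapply(matrices, function(x) {
    if (!is.null(label)) {
      keep <- readLabels(x) == label
      x <- BinMatrix(binOf(x),
                     callMatrix(x)[keep, , drop = FALSE],
                     labels = readLabels(x)[keep],
                     readIds = readIds(x)[keep])
    }
    computeBinCoverage(x)
  })
  do.call(rbind, rows)
}

#' Equalise informative-read depth between two libraries in a bin
#'
#' The deeper library's informative reads are randomly subsampled
#' (without replacement, seeded) down to the shallower library's
#' informative count, preventing depth imbalance from manufacturing
#' sample-specific clusters. Non-informative rows and single-library
#' matrices are left untouched.
#'
#' @param x A [BinMatrix-class].
#' @param seed Integer seed (RNG state is restored afterwards).
#' @return A [BinMatrix-class] with equalised informative depth.
#' @export
equalizeDepth <- function(x, seed = NULL) {
  libs <- sort(unique(readLabels(x)))
  if (length(libs) != 2L) return(x)
  inf <- informativeRows(x)
  nA <- sum(inf & readLabels(x) == libs[1])
  nB <- sum(inf & readLabels(x) == libs[2])
  if (nA == nB) return(x)
  target <- min(nA, nB)
  deeper <- if (nA > nB) libs[1] else libs[2]
  cand <- which(inf & readLabels(x) == deeper)
  keepCand <- .withSeed(seed, sort(sample(cand, target)))
  keep <- sort(c(which(!(seq_len(nrow(callMatrix(x))) %in% cand)), keepCand))
  BinMatrix(binOf(x), callMatrix(x)[keep, , drop = FALSE],
            labels = readLabels(x)[keep], readIds = readIds(x)[keep])
}

#' Group informative reads into clusters of identical methylation pattern
#'
#' Informative reads are grouped by exact pattern equality, pooling reads
#' across libraries; groups whose pooled size falls below
#' \code{minClusterSize} (default 4) are discarded. Output is sorted by
#' descending total count, ties broken by pattern lexicographic order.
#'
#' @param x A [BinMatrix-class].
#' @param minClusterSize Minimum pooled read count for a cluster.
#' @param libraries Library labels defining the count columns (default:
#'   sorted unique labels present in \code{x}).
#' @return data.frame with columns \code{pattern}, one \code{count_<lib>}
#'   per library, and \code{total}; the library vector is attached as
#'   attribute \code{"libraries"}.
#' @export
clusterReads <- function(x, minClusterSize = 4L, libraries = NULL) {
  inf <- informativeRows(x)
  m <- callMatrix(x)[inf, , drop = FALSE]
  labs <- readLabels(x)[inf]
  if (is.null(libraries)) libraries <- sort(unique(readLabels(x)))
  empty <- data.frame(pattern = character(0), stringsAsFactors = FALSE)
  for (l in libraries) empty[[paste0("count_", l)]] <- integer(0)
  empty$total <- integer(0)
  attr(empty, "libraries") <- libraries
  if (nrow(m) == 0L) return(empty)
  pats <- do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
  tab <- table(factor(pats), factor(labs, levels = libraries))
  total <- as.integer(rowSums(tab))
  keep <- total >= minClusterSize
  if (!any(keep)) return(empty)
  out <- data.frame(pattern = rownames(tab)[keep],
                    stringsAsFactors = FALSE)
  for (i in seq_along(libraries))
    out[[paste0("count_", libraries[i])]] <- as.integer(tab[keep, i])
  out$total <- total[keep]
  out <- out[order(-out$total, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "libraries") <- libraries
  out
}

#' Label clusters as shared or sample-specific
#'
#' In a two-library comparison a cluster is \code{A_only} if it contains
#' no reads from the second library, \code{B_only} if none from the first,
#' otherwise \code{shared}. In one-library mode every cluster is
#' \code{single_library}.
#'
#' @param clustersDf A cluster data.frame from [clusterReads()].
#' @return The data.frame with a \code{specificity} column added.
#' @export
labelSpecificity <- function(clustersDf) {
  libs <- attr(clustersDf, "libraries")
  if (is.null(libs)) stop("clustersDf must come from clusterReads()")
  if (length(libs) == 1L) {
    clustersDf$specificity <- rep("single_library", nrow(clustersDf))
    return(clustersDf)
  }
  cA <- clustersDf[[paste0("count_", libs[1])]]
  cB <- clustersDf[[paste0("count_", libs[2])]]
  clustersDf$specificity <- ifelse(cB == 0L, "A_only",
                            ifelse(cA == 0L, "B_only", "shared"))
  clustersDf
}

#' Classify clusters as major or minor within each library
#'
#' Within a bin, a cluster is \code{major} for a library if it holds at
#' least 50\% of that library's informative reads (after depth
#' equalisation), \code{minor} if fewer, and \code{absent} if it contains
#' no reads from that library.
#'
#' @param clustersDf A cluster data.frame from [clusterReads()].
#' @param binTotals Named integer vector of per-library informative-read
#'   totals for the bin (post-equalisation).
#' @return The data.frame with one \code{class_<lib>} column per library.
#' @export
classifyMajorMinor <- function(clustersDf, binTotals) {
  libs <- attr(clustersDf, "libraries")
  if (is.null(libs)) stop("clustersDf must come from clusterReads()")
  for (l in libs) {
    cnt <- clustersDf[[paste0("count_", l)]]
    tot <- binTotals[[l]]
    if (any(cnt > 0L) && (is.null(tot) || tot == 0L))
      stop("library '", l, "' has clustered reads but a zero bin total")
    cls <- rep("absent", nrow(clustersDf))
    pos <- cnt > 0L
    if (any(pos))
      cls[pos] <- ifelse(cnt[pos] / tot >= 0.5, "major", "minor")
    clustersDf[[paste0("class_", l)]] <- cls
  }
  clustersDf
}

## Per-bin phase 2 worker: coverage gate, equalisation, clustering,
## labelling. Returns NULL if the bin fails coverage.
.clusterBinPair <- function(x, libraries, minReads, minClusterSize, seed,
                            equalize) {
  if (binDensity(x) < 2L) return(NULL)
  inf <- informativeRows(x)
  labs <- readLabels(x)
  perLib <- vapply(libraries, function(l) sum(inf & labs == l), integer(1))
  if (any(perLib < minReads)) return(NULL)
  if (equalize && length(libraries) == 2L)
    x <- equalizeDepth(x, seed = seed)
  cl <- clusterReads(x, minClusterSize = minClusterSize,
                     libraries = libraries)
  inf <- informativeRows(x)
  labs <- readLabels(x)
  totals <- vapply(libraries, function(l) sum(inf & labs == l), integer(1))
  names(totals) <- libraries
  cl <- labelSpecificity(cl)
  cl <- classifyMajorMinor(cl, totals)
  n <- nrow(cl)
  twoLib <- length(libraries) == 2L
  list(
    chrom = rep(binChrom(x), n),
    bin_start = rep(binStart(x), n),
    bin_end = rep(binEnd(x), n),
    pattern = cl$pattern,
    count_A = cl[[paste0("count_", libraries[1])]],
    count_B = if (twoLib) cl[[paste0("count_", libraries[2])]]
              else rep(NA_integer_, n),
    specificity = cl$specificity,
    class_A = cl[[paste0("class_", libraries[1])]],
    class_B = if (twoLib) cl[[paste0("class_", libraries[2])]]
              else rep(NA_character_, n),
    bin_total_A = rep(totals[[1]], n),
    bin_total_B = if (twoLib) rep(totals[[2]], n) else rep(NA_integer_, n))
}

#' Cluster a set of bin matrices into a ClusterReport
#'
#' Runs the phase 2 pipeline over in-memory bin matrices: for each bin
#' with at least \code{minReads} informative reads in every library, the
#' two libraries' depths are equalised (two-library mode), informative
#' reads are clustered by pattern identity, and clusters are labelled for
#' specificity and major/minor class. Bins failing coverage are counted
#' as skipped.
#'
#' @param matrices List of [BinMatrix-class] objects.
#' @param minReads Minimum informative reads per library per bin
#'   (default 10).
#' @param minClusterSize Minimum pooled reads per cluster (default 4).
#' @param seed Integer seed for depth equalisation.
#' @param equalize Equalise per-bin depth between the two libraries
#'   (default TRUE; ignored in single-library mode).
#' @param libraries Optional explicit library labels (1 or 2); defaults to
#'   the sorted unique labels found across all matrices.
#' @return A [ClusterReport-class].
#' @export
clusterBins <- function(matrices, minReads = 10L, minClusterSize = 4L,
                        seed = NULL, equalize = TRUE, libraries = NULL) {
  if (is.null(libraries)) {
    libraries <- sort(unique(unlist(lapply(matrices, readLabels))))
    if (length(libraries) == 0L) libraries <- "A"
  }
  if (!length(libraries) %in% 1:2)
    stop("clustering supports one or two libraries, got ",
         length(libraries))
  rows <- vector("list", length(matrices))
  nskip <- 0L
  for (i in seq_along(matrices)) {
    binSeed <- if (is.null(seed)) NULL else (as.numeric(seed) + i) %% 2147483647
    r <- .clusterBinPair(matrices[[i]], libraries, minReads,
                         minClusterSize, binSeed, equalize)
    if (is.null(r)) nskip <- nskip + 1L else rows[[i]] <- r
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  colNames <- c("chrom", "bin_start", "bin_end", "pattern", "count_A",
                "count_B", "specificity", "class_A", "class_B",
                "bin_total_A", "bin_total_B")
  cl <- if (length(rows)) {
    do.call(S4Vectors::DataFrame,
            c(lapply(stats::setNames(colNames, colNames), function(cn)
                unlist(lapply(rows, `[[`, cn), use.names = FALSE)),
              list(check.names = FALSE)))
  } else
    S4Vectors::DataFrame(chrom = character(0), bin_start = integer(0),
                         bin_end = integer(0), pattern = character(0),
                         count_A = integer(0), count_B = integer(0),
                         specificity = character(0), class_A = character(0),
                         class_B = character(0), bin_total_A = integer(0),
                         bin_total_B = integer(0))
  new("ClusterReport", clusters = cl,
      params = list(mode = if (length(libraries) == 2L) "two-library"
                           else "one-library",
                    libraries = libraries, min_reads = as.integer(minReads),
                    min_cluster_size = as.integer(minClusterSize),
                    seed = seed, equalize = equalize),
      nBinsProcessed = as.integer(length(matrices) - nskip),
      nBinsSkipped = nskip)
}

#' Compare two WGBS libraries bin by bin
#'
#' Full two-library analysis from indexed BAM files: reads are parsed
#' once per file, distributed into the supplied bins, and clustered with
#' [clusterBins()]. Only bins with at least \code{minReads} informative
#' reads in \emph{both} libraries are analysed.
#'
#' @param bamA,bamB Paths to indexed BAM files with call-string tags.
#' @param bins List of [BinSpec-class] objects (density >= 2).
#' @param minReads,minClusterSize,seed,equalize See [clusterBins()].
#' @param labels Length-2 library labels (default \code{c("A","B")}).
#' @param tag Call-string tag name.
#' @return A [ClusterReport-class].
#' @export
compareLibraries <- function(bamA, bamB, bins, minReads = 10L,
                             minClusterSize = 4L, seed = NULL,
                             equalize = TRUE, labels = c("A", "B"),
                             tag = "XM") {
  callsA <- readBamCalls(bamA, label = labels[1], tag = tag)$calls
  callsB <- readBamCalls(bamB, label = labels[2], tag = tag)$calls
  mats <- binMatrices(rbind(callsA, callsB), bins)
  clusterBins(mats, minReads = minReads, minClusterSize = minClusterSize,
              seed = seed, equalize = equalize, libraries = labels)
}

#' Fraction of clusters unique to each input library
#'
#' @param report A two-library [ClusterReport-class].
#' @return Named numeric vector: the proportion of all clusters labelled
#'   \code{A_only} and \code{B_only} respectively.
#' @export
summarizeUniqueFraction <- function(report) {
  if (!identical(reportParams(report)$mode, "two-library"))
    stop("unique-cluster fractions are defined for two-library reports")
  cl <- clusters(report)
  if (nrow(cl) == 0L)
    stop("empty report: no clusters to summarise")
  c(A = mean(cl$specificity == "A_only"),
    B = mean(cl$specificity == "B_only"))
}

#' Write a cluster report as TSV with a JSON parameter sidecar
#'
#' @param report A [ClusterReport-class].
#' @param file Output TSV path; parameters are written to
#'   \code{<file>.json}.
#' @return Invisibly, the TSV path.
#' @export
writeClusterReport <- function(report, file) {
  utils::write.table(as.data.frame(clusters(report)), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- reportParams(report)
  meta$n_bins_processed <- nBinsProcessed(report)
  meta$n_bins_skipped <- nBinsSkipped(report)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(file)
}

#' Read a cluster report written by [writeClusterReport()]
#'
#' @param file TSV path.
#' @return A [ClusterReport-class] (parameters restored from the JSON
#'   sidecar when present).
#' @export
readClusterReport <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(pattern = "character"))
  params <- list()
  side <- paste0(file, ".json")
  nproc <- NA_integer_; nskip <- NA_integer_
  if (file.exists(side)) {
    params <- jsonlite::read_json(side, simplifyVector = TRUE)
    nproc <- as.integer(params$n_bins_processed)
    nskip <- as.integer(params$n_bins_skipped)
    params$n_bins_processed <- NULL
    params$n_bins_skipped <- NULL
  }
  new("ClusterReport", clusters = S4Vectors::DataFrame(df),
      params = as.list(params),
      nBinsProcessed = if (is.na(nproc)) 0L else nproc,
      nBinsSkipped = if (is.na(nskip)) 0L else nskip)
}
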