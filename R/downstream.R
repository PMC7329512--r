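## ---- feature tables for mixture deconvolution -------------------------

#' Read a BED file of intervals (e.g. DMRs)
#'
#' @param file Path to a 3+ column BED file (0-based, half-open).
#' @return A [GenomicRanges::GRanges-class].
#' @export
readBED <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L || is.na(suppressWarnings(as.integer(p[2]))) ||
        is.na(suppressWarnings(as.integer(p[3]))))
      stop("malformed BED line ", i, " in '", file, "'")
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  s <- as.integer(vapply(parts, `[`, character(1), 2L))
  e <- as.integer(vapply(parts, `[`, character(1), 3L))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1L, e))
}

#' Build a samples x (bin, pattern) read-count feature table
#'
#' Each single-library cluster report contributes one row; there is one
#' column for every (bin, pattern) combination observed in any report,
#' valued by the cluster's read count (0 where absent). Columns whose bin
#' overlaps a DMR interval are removed, making the features orthogonal to
#' conventional differential methylation.
#'
#' @param reports Named list of single-library [ClusterReport-class]
#'   objects (one per mixture sample).
#' @param dmr Optional [GenomicRanges::GRanges-class] or BED path of
#'   regions to exclude (half-open overlap).
#' @param proportions Optional numeric vector of true cell-type-A
#'   proportions, attached as attribute \code{"proportions"}.
#' @return Numeric matrix (samples x features) with column names
#'   \code{"chrom:start-end|pattern"}.
#' @export
buildFeatureTable <- function(reports, dmr = NULL, proportions = NULL) {
  if (is.character(dmr)) dmr <- readBED(dmr)
  rows <- lapply(reports, function(r) {
    cl <- clusters(r)
    key <- paste0(cl$chrom, ":", cl$bin_start, "-", cl$bin_end, "|",
                  cl$pattern)
    cnt <- cl$count_A
    if (!all(is.na(cl$count_B)))
      cnt <- cnt + ifelse(is.na(cl$count_B), 0L, cl$count_B)
    stats::setNames(as.numeric(cnt), key)
  })
  cols <- sort(unique(unlist(lapply(rows, names))))
  tab <- matrix(0, length(rows), length(cols),
                dimnames = list(names(reports), cols))
  for (i in seq_along(rows))
    tab[i, names(rows[[i]])] <- rows[[i]]
  if (!is.null(dmr) && length(cols)) {
    loc <- sub("\\|.*$", "", cols)
    chrom <- sub(":.*$", "", loc)
    rng <- sub("^.*:", "", loc)
    s <- as.integer(sub("-.*$", "", rng))
    e <- as.integer(sub("^.*-", "", rng))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1L, e))
    hit <- GenomicRanges::countOverlaps(gr, dmr) > 0L
    tab <- tab[, !hit, drop = FALSE]
  }
  if (!is.null(proportions)) attr(tab, "proportions") <- proportions
  tab
}

#' Align a test feature table to a training table's columns
#'
#' Test columns are restricted and reordered to the training column
#' order; training-only columns are added to the test table and set to
#' zero; test-only columns are dropped.
#'
#' @param trainTable,testTable Matrices from [buildFeatureTable()].
#' @return The aligned test matrix (same columns as \code{trainTable}).
#' @export
alignFeatures <- function(trainTable, testTable) {
  cols <- colnames(trainTable)
  out <- matrix(0, nrow(testTable), length(cols),
                dimnames = list(rownames(testTable), cols))
  shared <- intersect(cols, colnames(testTable))
  out[, shared] <- testTable[, shared, drop = FALSE]
  attr(out, "proportions") <- attr(testTable, "proportions")
  out
}

## ---- proportion estimation --------------------------------------------

.projectPCs <- function(x, center, rotation) {
  sweep(x, 2L, center) %*% rotation
}

#' Fit a principal-components regression for mixture proportions
#'
#' Features are centred and projected onto the top \code{nComponents}
#' principal components; a multivariate linear regression maps components
#' to the true proportion. Cross-validated RMSE is computed with the PCA
#' refit on the training rows of each fold, so no information leaks from
#' held-out rows; the final model is refit on all rows.
#'
#' @param table Feature matrix from [buildFeatureTable()].
#' @param proportions True proportions; defaults to the table's
#'   \code{"proportions"} attribute.
#' @param nComponents Retained components (default 20).
#' @param folds CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return A [ProportionModel-class] with slot \code{cvRMSE}.
#' @export
fitProportionModel <- function(table, proportions = NULL,
                               nComponents = 20L, folds = 5L, seed = 1L) {
  if (is.null(proportions)) proportions <- attr(table, "proportions")
  if (is.null(proportions))
    stop("true proportions are required to fit the model")
  n <- nrow(table)
  if (n < nComponents + 1L)
    stop("fewer samples (", n, ") than components + 1; lower nComponents")
  foldId <- .withSeed(seed, sample(rep_len(seq_len(folds), n)))
  preds <- numeric(n)
  for (k in seq_len(folds)) {
    tr <- foldId != k
    fitK <- .pcrFit(table[tr, , drop = FALSE], proportions[tr],
                    nComponents)
    preds[!tr] <- .pcrPredict(fitK, table[!tr, , drop = FALSE])
  }
  cvRMSE <- sqrt(mean((preds - proportions)^2))
  fit <- .pcrFit(table, proportions, nComponents)
  new("ProportionModel", center = fit$center, rotation = fit$rotation,
      coefficients = fit$coef, columns = colnames(table),
      nComponents = as.integer(ncol(fit$rotation)), cvRMSE = cvRMSE)
}

.pcrFit <- function(x, p, nComponents) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE,
                      rank. = min(nComponents, nrow(x) - 1L, ncol(x)))
  scores <- pc$x
  df <- data.frame(p = p, scores)
  lmfit <- stats::lm(p ~ ., data = df)
  list(center = pc$center, rotation = pc$rotation,
       coef = stats::coef(lmfit))
}

.pcrPredict <- function(fit, x) {
  scores <- .projectPCs(x, fit$center, fit$rotation)
  beta <- fit$coef
  beta[is.na(beta)] <- 0
  pred <- drop(cbind(1, scores) %*% beta)
  pmin(pmax(pred, 0), 1)
}

#' Predict mixture proportions with a fitted model
#'
#' @param model A [ProportionModel-class].
#' @param table Feature matrix aligned to the training columns via
#'   [alignFeatures()].
#' @return Numeric vector of predictions, clipped to [0, 1].
#' @export
predictProportions <- function(model, table) {
  if (!identical(colnames(table), model@columns))
    stop("feature columns do not match the training table; ",
         "use alignFeatures() first")
  .pcrPredict(list(center = model@center, rotation = model@rotation,
                   coef = model@coefficients), table)
}

## ---- gene selection and promoter features -----------------------------

#' Select differentially expressed genes by log-fold-change outliers
#'
#' Computes \eqn{\Delta = \log_2(\mathrm{FPKM}_A + pc) -
#' \log_2(\mathrm{FPKM}_B + pc)} and selects genes whose \eqn{\Delta}
#' deviates from the mean by more than \code{sdMult} standard deviations;
#' the binary label is the sign of \eqn{\Delta} (which cell type
#' expresses the gene more highly).
#'
#' @param fpkmA,fpkmB Non-negative FPKM vectors over a matched gene
#'   universe.
#' @param sdMult Standard-deviation multiplier (default 2).
#' @param pseudocount Added before the log (default 1).
#' @param geneIds Optional gene identifiers.
#' @return data.frame with \code{gene_id}, \code{fpkm_A}, \code{fpkm_B},
#'   \code{delta_log2}, \code{selected}, \code{label} ("A"/"B").
#' @export
selectDifferentialGenes <- function(fpkmA, fpkmB, sdMult = 2,
                                    pseudocount = 1, geneIds = NULL) {
  if (any(fpkmA < 0) || any(fpkmB < 0))
    stop("FPKM values must be non-negative")
  if (is.null(geneIds)) geneIds <- sprintf("gene%d", seq_along(fpkmA))
  delta <- log2(fpkmA + pseudocount) - log2(fpkmB + pseudocount)
  sel <- abs(delta - mean(delta)) > sdMult * stats::sd(delta)
  data.frame(gene_id = geneIds, fpkm_A = fpkmA, fpkm_B = fpkmB,
             delta_log2 = delta, selected = sel,
             label = ifelse(delta > 0, "A", "B"),
             stringsAsFactors = FALSE)
}

#' Build promoter methylation and cluster features per gene
#'
#' For each gene: the mean methylation of all promoter-window CpGs per
#' cell type (from per-CpG coverage tables); one count column per
#' (pattern, specificity) combination over all clusters whose bin
#' intersects the promoter window; and, optionally, decile-frequency
#' vectors (fraction of promoter CpGs in [0,10), [10,20), ..., [90,100]
#' percent methylation) per cell type. The default promoter window is
#' the half-open interval [TSS - window, TSS + window); with
#' \code{upstreamOnly = TRUE} a strand-aware window covering
#' \code{upstreamBp} upstream of the TSS is used instead.
#'
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{tss}
#'   (0-based), \code{strand}.
#' @param clusterReport A [ClusterReport-class] (two-library comparison of
#'   the cell types).
#' @param covA,covB Bismark-style coverage data.frames (see
#'   [readBismarkCov()]) for cell types A and B.
#' @param window Half-width of the symmetric promoter window in bp
#'   (default 3000).
#' @param includeDeciles Add the 2 x 10 decile-frequency features.
#' @param upstreamOnly Use a strand-aware upstream-only window.
#' @param upstreamBp Size of the upstream window (default 500).
#' @return List with \code{features} (genes x features matrix; columns
#'   \code{mean_meth_A}, \code{mean_meth_B}, optional decile columns,
#'   then \code{"pattern|specificity"} counts), \code{genes} (kept gene
#'   ids) and \code{nDropped} (genes with no promoter CpGs).
#' @export
buildPromoterFeatures <- function(genes, clusterReport, covA, covB,
                                  window = 3000L, includeDeciles = FALSE,
                                  upstreamOnly = FALSE, upstreamBp = 500L) {
  cl <- clusters(clusterReport)
  winOf <- function(g) {
    if (upstreamOnly) {
      if (identical(g$strand, "-")) c(g$tss + 1L, g$tss + 1L + upstreamBp)
      else c(g$tss - upstreamBp, g$tss)
    } else c(g$tss - window, g$tss + window)
  }
  decBreaks <- c(seq(0, 90, 10), 100.000001)
  feats <- list(); kept <- character(0); nDropped <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    w <- winOf(g)
    inWin <- function(cov) {
      pos0 <- cov$start - 1L
      cov[cov$chrom == g$chrom & pos0 >= w[1] & pos0 < w[2], ,
          drop = FALSE]
    }
    ca <- inWin(covA); cb <- inWin(covB)
    if (nrow(ca) == 0L || nrow(cb) == 0L) { nDropped <- nDropped + 1L; next }
    row <- c(mean_meth_A = mean(ca$meth_pct),
             mean_meth_B = mean(cb$meth_pct))
    if (includeDeciles) {
      dA <- tabulate(findInterval(ca$meth_pct, decBreaks,
                                  rightmost.closed = FALSE), 10L) / nrow(ca)
      dB <- tabulate(findInterval(cb$meth_pct, decBreaks,
                                  rightmost.closed = FALSE), 10L) / nrow(cb)
      names(dA) <- paste0("decile_A_", 1:10)
      names(dB) <- paste0("decile_B_", 1:10)
      row <- c(row, dA, dB)
    }
    sel <- cl$chrom == g$chrom & cl$bin_start < w[2] & cl$bin_end > w[1]
    if (any(sel)) {
      sub <- cl[sel, , drop = FALSE]
      cnt <- sub$count_A + ifelse(is.na(sub$count_B), 0L, sub$count_B)
      key <- paste0(sub$pattern, "|", sub$specificity)
      agg <- tapply(as.numeric(cnt), key, sum)
      row <- c(row, stats::setNames(as.numeric(agg), names(agg)))
    }
    feats[[g$gene_id]] <- row
    kept <- c(kept, g$gene_id)
  }
  cols <- unique(unlist(lapply(feats, names)))
  base <- c("mean_meth_A", "mean_meth_B")
  cols <- c(base, sort(setdiff(cols, base)))
  mat <- matrix(0, length(feats), length(cols),
                dimnames = list(kept, cols))
  for (id in kept) mat[id, names(feats[[id]])] <- feats[[id]]
  list(features = mat, genes = kept, nDropped = nDropped)
}

## ---- expression prediction --------------------------------------------

.fitForest <- function(x, y, numTrees, maxDepth, seed) {
  ranger::ranger(x = x, y = y, num.trees = numTrees,
                 max.depth = maxDepth, probability = TRUE,
                 seed = seed, num.threads = 1L)
}

.forestGridSearch <- function(x, y, grid, folds, seed) {
  combos <- expand.grid(num_trees = grid$num_trees,
                        max_depth = grid$max_depth)
  foldId <- .withSeed(seed, sample(rep_len(seq_len(folds), nrow(x))))
  score <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    aucs <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- foldId != k
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
        aucs[k] <- NA; next
      }
      fit <- .fitForest(x[tr, , drop = FALSE], y[tr],
                        combos$num_trees[ci], combos$max_depth[ci], seed)
      p <- stats::predict(fit, data = x[!tr, , drop = FALSE],
                          num.threads = 1L)$predictions[, 2L]
      aucs[k] <- .auc(as.integer(y[!tr]) - 1L, p)
    }
    score[ci] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(score)
  list(num_trees = combos$num_trees[best],
       max_depth = combos$max_depth[best], cv_auc = score[best])
}

#' Random-forest prediction of binary gene-expression labels
#'
#' Trains a probability forest on per-gene promoter features to predict
#' which cell type expresses each gene more highly. Hyperparameters
#' (forest size, tree depth) are chosen once by grid search with k-fold
#' cross-validation, then evaluated over \code{nSplits} random 80/20
#' train-test splits (AUC on each held-out 20\%). With
#' \code{nested = TRUE} a nested cross-validation is run instead: the
#' grid search is repeated independently inside each outer fold. With
#' \code{permute = TRUE} labels are shuffled (seeded) before everything
#' else, providing the negative control.
#'
#' @param features Numeric genes x features matrix.
#' @param labels Binary labels (two levels).
#' @param nSplits Number of random 80/20 splits (default 100).
#' @param grid Hyperparameter grid: list with \code{num_trees},
#'   \code{max_depth} (0 = unlimited depth).
#' @param cvFolds Folds for the grid search (default 10).
#' @param nested Run nested cross-validation instead of random splits.
#' @param nestedFolds Outer folds in nested mode (default 10).
#' @param permute Shuffle labels first (negative control).
#' @param seed Integer seed.
#' @return List with \code{auc} (per split or per outer fold),
#'   \code{best} (chosen hyperparameters; NULL in nested mode),
#'   \code{mode}, \code{permuted}.
#' @export
trainExpressionModel <- function(features, labels, nSplits = 100L,
                                 grid = list(num_trees = c(10, 50, 100),
                                             max_depth = c(5, 25, 0)),
                                 cvFolds = 10L, nested = FALSE,
                                 nestedFolds = 10L, permute = FALSE,
                                 seed = 1L) {
  y <- factor(labels)
  if (nlevels(y) != 2L)
    stop("labels must have exactly two classes")
  if (permute)
    y <- .withSeed((as.numeric(seed) * 7919) %% 2147483647, sample(y))
  x <- as.matrix(features)
  n <- nrow(x)
  if (nested) {
    foldId <- .withSeed(seed, sample(rep_len(seq_len(nestedFolds), n)))
    aucs <- numeric(nestedFolds)
    for (k in seq_len(nestedFolds)) {
      tr <- foldId != k
      best <- .forestGridSearch(x[tr, , drop = FALSE], y[tr], grid,
                                cvFolds, seed + k)
      fit <- .fitForest(x[tr, , drop = FALSE], y[tr], best$num_trees,
                        best$max_depth, seed + k)
      p <- stats::predict(fit, data = x[!tr, , drop = FALSE],
                          num.threads = 1L)$predictions[, 2L]
      aucs[k] <- .auc(as.integer(y[!tr]) - 1L, p)
    }
    return(list(auc = aucs, best = NULL, mode = "nested",
                permuted = permute))
  }
  best <- .forestGridSearch(x, y, grid, cvFolds, seed)
  aucs <- numeric(nSplits)
  for (s in seq_len(nSplits)) {
    idx <- .withSeed(seed + s, sample.int(n, round(0.8 * n)))
    ytr <- y[idx]
    if (nlevels(droplevels(ytr)) < 2L ||
        nlevels(droplevels(y[-idx])) < 2L) { aucs[s] <- NA; next }
    fit <- .fitForest(x[idx, , drop = FALSE], ytr, best$num_trees,
                      best$max_depth, seed + s)
    p <- stats::predict(fit, data = x[-idx, , drop = FALSE],
                        num.threads = 1L)$predictions[, 2L]
    aucs[s] <- .auc(as.integer(y[-idx]) - 1L, p)
  }
  list(auc = aucs, best = best, mode = "splits", permuted = permute)
}
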