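## ---- internal helpers -------------------------------------------------

.asCalls <- function(x) {
  if (is(x, "BinMatrix")) callMatrix(x) else x
}

## ROC AUC for binary labels in {0,1}; NA when only one class present.
.auc <- function(labels, scores) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(response = factor(labels, levels = c(0, 1)),
                       predictor = scores, levels = c("0", "1"),
                       direction = "<", quiet = TRUE))
}

## Area under the precision-recall curve (average precision).
.auprc <- function(labels, scores) {
  if (sum(labels == 1L) == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab == 1L)
  precision <- tp / seq_along(lab)
  sum(precision[lab == 1L]) / sum(lab == 1L)
}

## Lexicographic pattern index of the rows of a 0/1 matrix:
## the first CpG is the most significant bit; "00" -> 1, "01" -> 2, ...
.patternIndex <- function(m) {
  d <- ncol(m)
  as.integer(m %*% 2^((d - 1):0)) + 1L
}

## ---- mask harvesting --------------------------------------------------

#' Harvest missingness masks from observed bin matrices
#'
#' Records, for every matrix containing at least one missing call, the
#' set of missing (row, column) cells as a mask, retrievable by matrix
#' shape. These masks reproduce the real missingness structure (reads
#' partially overlapping a bin) and are later overlaid on fully observed
#' matrices to create labelled training data.
#'
#' @param matrices List of [BinMatrix-class] objects or plain call
#'   matrices.
#' @return A named list keyed by \code{"<n_reads>x<d>"}; each element is a
#'   list of 2-column index matrices (row, col).
#' @export
collectMasks <- function(matrices) {
  lib <- list()
  for (x in matrices) {
    m <- .asCalls(x)
    cells <- which(m == -1L, arr.ind = TRUE)
    if (nrow(cells) == 0L) next
    key <- paste0(nrow(m), "x", ncol(m))
    lib[[key]] <- c(lib[[key]], list(unname(cells)))
  }
  lib
}

## ---- per-CpG feature encoding ----------------------------------------

#' Encode one missing read-level CpG as a feature vector
#'
#' Expands the cell (\code{row}, \code{col}) of a partially observed bin
#' matrix into a 1-D feature vector: the mean of the observed states on
#' the read, the mean of the observed states at the CpG position, the raw
#' row and column indices, the number of observed CpGs on the read, the
#' full row of states (with -1 at missing cells), and the "read
#' encodings" -- the relative proportions of each of the \eqn{2^d}
#' possible fully observed patterns among the complete reads of the
#' matrix (all-zero when no complete read exists). Patterns are indexed
#' in lexicographic order (first CpG most significant).
#'
#' @param m A call matrix or [BinMatrix-class].
#' @param row,col 1-based indices of a missing cell.
#' @return Named numeric vector of length \eqn{5 + d + 2^d}.
#' @export
encodeCpgFeatures <- function(m, row, col) {
  m <- .asCalls(m)
  if (m[row, col] != -1L) stop("cell (", row, ",", col, ") is not missing")
  drop(.encodeCells(m, cbind(row, col)))
}

## Batch encoder: cells is a 2-column (row, col) index matrix; all cells
## must be missing in m. Returns one feature row per cell.
.encodeCells <- function(m, cells) {
  d <- ncol(m)
  obs <- m != -1L
  rowSumObs <- rowSums(m * obs)
  rowCntObs <- rowSums(obs)
  colSumObs <- colSums(m * obs)
  colCntObs <- colSums(obs)
  complete <- rowCntObs == d
  enc <- numeric(2^d)
  if (any(complete)) {
    idx <- .patternIndex(m[complete, , drop = FALSE])
    tab <- tabulate(idx, nbins = 2^d)
    enc <- tab / sum(tab)
  }
  nc <- nrow(cells)
  out <- matrix(0, nc, 5L + d + 2^d)
  colnames(out) <- c("row_mean", "col_mean", "row_index", "col_index",
                     "n_observed_on_read", paste0("state_", seq_len(d)),
                     paste0("enc_", seq_len(2^d)))
  r <- cells[, 1]; cc <- cells[, 2]
  rm_ <- ifelse(rowCntObs[r] > 0L, rowSumObs[r] / pmax(rowCntObs[r], 1L), 0.5)
  cm_ <- ifelse(colCntObs[cc] > 0L, colSumObs[cc] / pmax(colCntObs[cc], 1L), 0.5)
  out[, 1] <- rm_
  out[, 2] <- cm_
  out[, 3] <- r
  out[, 4] <- cc
  out[, 5] <- rowCntObs[r]
  out[, 5L + seq_len(d)] <- m[r, , drop = FALSE]
  out[, 5L + d + seq_len(2^d)] <- matrix(enc, nc, 2^d, byrow = TRUE)
  out
}

## ---- training-set construction ---------------------------------------

#' Build a labelled training set by masking complete matrices
#'
#' For each fully observed matrix, a harvested mask of the same shape is
#' sampled (seeded) and overlaid; every artificially hidden cell yields
#' one training example: its feature encoding on the masked matrix plus
#' its known true state. Examples are grouped by CpG density and capped
#' at \code{maxPerDensity} by seeded subsampling.
#'
#' @param completeMatrices List of call matrices / [BinMatrix-class]
#'   objects containing no -1.
#' @param maskLibrary Mask library from [collectMasks()].
#' @param seed Integer seed.
#' @param maxPerDensity Cap on examples per density (default 10000).
#' @return List with \code{densities} (per density: list \code{x} feature
#'   matrix, \code{y} integer labels) and \code{nSkippedNoMask}.
#' @export
buildTrainingSet <- function(completeMatrices, maskLibrary, seed = 1L,
                             maxPerDensity = 10000L) {
  .withSeed(seed, {
    feats <- list(); labs <- list()
    nskip <- 0L
    for (x in completeMatrices) {
      m <- .asCalls(x)
      if (any(m == -1L))
        stop("complete matrices must contain no missing values")
      key <- paste0(nrow(m), "x", ncol(m))
      masks <- maskLibrary[[key]]
      if (is.null(masks)) { nskip <- nskip + 1L; next }
      mask <- masks[[sample.int(length(masks), 1L)]]
      truth <- m[mask]
      masked <- m
      masked[mask] <- -1L
      f <- .encodeCells(masked, mask)
      dk <- as.character(ncol(m))
      feats[[dk]] <- c(feats[[dk]], list(f))
      labs[[dk]] <- c(labs[[dk]], list(truth))
    }
    densities <- list()
    for (dk in names(feats)) {
      x <- do.call(rbind, feats[[dk]])
      y <- as.integer(unlist(labs[[dk]]))
      if (nrow(x) > maxPerDensity) {
        keep <- sort(sample.int(nrow(x), maxPerDensity))
        x <- x[keep, , drop = FALSE]
        y <- y[keep]
      }
      densities[[dk]] <- list(x = x, y = y)
    }
    list(densities = densities, nSkippedNoMask = nskip)
  })
}

#' Assemble masked training data from a library's own bins
#'
#' Convenience wrapper over [collectMasks()] and [buildTrainingSet()]:
#' masks are harvested from every matrix with missing calls; complete
#' matrices are formed from the informative reads of bins holding at
#' least \code{minReads} of them; masks of matching shape are overlaid to
#' produce labelled examples.
#'
#' @param matrices List of [BinMatrix-class] from one library.
#' @param minReads Minimum informative reads for a bin to contribute a
#'   complete matrix (default 10).
#' @param seed Integer seed.
#' @param maxPerDensity Per-density example cap.
#' @return As [buildTrainingSet()].
#' @export
prelimTrainingData <- function(matrices, minReads = 10L, seed = 1L,
                               maxPerDensity = 10000L) {
  maskLib <- collectMasks(matrices)
  complete <- list()
  for (x in matrices) {
    inf <- informativeRows(x)
    if (sum(inf) >= minReads)
      complete <- c(complete, list(callMatrix(x)[inf, , drop = FALSE]))
  }
  buildTrainingSet(complete, maskLib, seed = seed,
                   maxPerDensity = maxPerDensity)
}

## ---- model training ---------------------------------------------------

#' Train per-density read-level imputation models
#'
#' For each CpG density present in the training set: the examples are
#' split 80/20 (seeded); a grid search over forest size and tree depth is
#' scored by mean k-fold cross-validated AUC on the 80\% partition; the
#' winning configuration is refit on the full 80\% and evaluated (AUC,
#' AUPRC) on the held-out 20\%.
#'
#' @param training Output of [buildTrainingSet()].
#' @param grid List with \code{num_trees} and \code{max_depth} vectors.
#'   Defaults to trees \{10, 50, 100, 500, 1000\} by depth
#'   \{1, 5, 10, 20, 30\}.
#' @param folds Cross-validation folds for the grid search (default 5).
#' @param holdout Held-out fraction (default 0.2).
#' @param seed Integer seed.
#' @return An [ImputationModel-class].
#' @export
trainImputationModel <- function(training,
                                 grid = list(num_trees = c(10, 50, 100, 500, 1000),
                                             max_depth = c(1, 5, 10, 20, 30)),
                                 folds = 5L, holdout = 0.2, seed = 1L) {
  densities <- training$densities
  models <- list(); chosen <- list()
  met <- list()
  combos <- expand.grid(num_trees = grid$num_trees,
                        max_depth = grid$max_depth)
  densities <- densities[order(as.integer(names(densities)))]
  for (dk in names(densities)) {
    x <- densities[[dk]]$x
    y <- densities[[dk]]$y
    if (length(unique(y)) < 2L)
      stop("training set for density ", dk, " contains a single class")
    n <- nrow(x)
    split <- .withSeed(seed, sample.int(n, round(n * (1 - holdout))))
    xtr <- x[split, , drop = FALSE]; ytr <- y[split]
    xte <- x[-split, , drop = FALSE]; yte <- y[-split]
    foldId <- .withSeed(seed + 1L,
                        sample(rep_len(seq_len(folds), nrow(xtr))))
    cvAUC <- numeric(nrow(combos))
    for (ci in seq_len(nrow(combos))) {
      aucs <- numeric(folds)
      for (k in seq_len(folds)) {
        tr <- foldId != k
        if (length(unique(ytr[tr])) < 2L) { aucs[k] <- NA; next }
        fit <- ranger::ranger(x = xtr[tr, , drop = FALSE],
                              y = factor(ytr[tr], levels = c(0, 1)),
                              num.trees = combos$num_trees[ci],
                              max.depth = combos$max_depth[ci],
                              probability = TRUE, seed = seed,
                              num.threads = 1L)
        p <- stats::predict(fit, data = xtr[!tr, , drop = FALSE],
                            num.threads = 1L)$predictions[, "1"]
        aucs[k] <- .auc(ytr[!tr], p)
      }
      cvAUC[ci] <- mean(aucs, na.rm = TRUE)
    }
    best <- which.max(cvAUC)
    fit <- ranger::ranger(x = xtr, y = factor(ytr, levels = c(0, 1)),
                          num.trees = combos$num_trees[best],
                          max.depth = combos$max_depth[best],
                          probability = TRUE, seed = seed,
                          num.threads = 1L)
    pte <- stats::predict(fit, data = xte,
                          num.threads = 1L)$predictions[, "1"]
    models[[dk]] <- fit
    chosen[[dk]] <- list(num_trees = combos$num_trees[best],
                         max_depth = combos$max_depth[best],
                         cv_auc = cvAUC[best])
    met[[dk]] <- data.frame(density = as.integer(dk),
                            n_train = nrow(xtr), n_heldout = nrow(xte),
                            auc = .auc(yte, pte), auprc = .auprc(yte, pte),
                            auc_baseline = .auc(yte, xte[, "col_mean"]))
  }
  new("ImputationModel", models = models, chosen = chosen,
      metrics = S4Vectors::DataFrame(do.call(rbind, met)),
      trainLibrary = if (is.null(training$library)) "unknown"
                     else training$library,
      seed = as.integer(seed))
}

## ---- prediction, baseline, gating ------------------------------------

#' Prediction confidence of a methylation probability
#'
#' \eqn{C = |2(y - 0.5)|}: 0 when the model is maximally unsure
#' (\eqn{y = 0.5}), 1 when certain.
#'
#' @param y Probability (or vector of probabilities) of methylation in
#'   [0, 1].
#' @return Confidence value(s) in [0, 1].
#' @examples
#' confidence(c(0.5, 0.8, 1))
#' @export
confidence <- function(y) {
  if (any(y < 0 | y > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  abs(2 * (y - 0.5))
}

#' Column-mean baseline predictor for a missing read-level CpG
#'
#' Predicts the methylation probability of a missing cell as the average
#' observed methylation at that CpG position (the column mean), the
#' natural no-model baseline.
#'
#' @param m Call matrix or [BinMatrix-class].
#' @param row,col 1-based indices of the missing cell.
#' @return List with \code{y} (probability; 0.5 for an empty column) and
#'   \code{C} (confidence).
#' @export
columnMeanBaseline <- function(m, row, col) {
  m <- .asCalls(m)
  v <- m[, col]
  obs <- v != -1L
  y <- if (any(obs)) mean(v[obs]) else 0.5
  list(y = y, C = confidence(y))
}

#' Predict methylation probabilities for the missing cells of a matrix
#'
#' @param model An [ImputationModel-class].
#' @param x Call matrix or [BinMatrix-class].
#' @return data.frame with \code{row}, \code{col}, \code{y}, \code{C};
#'   zero rows when nothing is missing. \code{NULL} when the matrix
#'   density has no trained model.
#' @export
predictMissing <- function(model, x) {
  m <- .asCalls(x)
  dk <- as.character(ncol(m))
  if (!dk %in% names(model@models)) return(NULL)
  cells <- which(m == -1L, arr.ind = TRUE)
  if (nrow(cells) == 0L)
    return(data.frame(row = integer(0), col = integer(0),
                      y = numeric(0), C = numeric(0)))
  f <- .encodeCells(m, cells)
  y <- stats::predict(model@models[[dk]], data = f,
                      num.threads = 1L)$predictions[, "1"]
  data.frame(row = cells[, 1], col = cells[, 2], y = y,
             C = confidence(y))
}

#' Impute missing read-level CpG calls with confidence gating
#'
#' Each missing cell whose prediction confidence exceeds
#' \code{confThreshold} is set to 1 if \eqn{y > 0.5}, else 0; low
#' confidence cells stay missing and observed cells are never modified.
#' Matrices whose density has no trained model are returned unchanged
#' (flagged via attribute \code{"unimputed"}).
#'
#' @param model An [ImputationModel-class].
#' @param x A [BinMatrix-class].
#' @param confThreshold Confidence gate (default 0.6; predictions must
#'   exceed it strictly).
#' @return A [BinMatrix-class] with high-confidence cells filled in.
#' @export
imputeMatrix <- function(model, x, confThreshold = 0.6) {
  pred <- predictMissing(model, x)
  if (is.null(pred)) {
    attr(x, "unimputed") <- TRUE
    return(x)
  }
  m <- callMatrix(x)
  pass <- pred$C > confThreshold
  if (any(pass))
    m[cbind(pred$row[pass], pred$col[pass])] <-
      as.integer(pred$y[pass] > 0.5)
  BinMatrix(binOf(x), m, labels = readLabels(x), readIds = readIds(x))
}

#' Impute a list of bin matrices
#'
#' @param model An [ImputationModel-class].
#' @param matrices List of [BinMatrix-class].
#' @param confThreshold Confidence gate.
#' @return List of imputed matrices.
#' @export
imputeMatrices <- function(model, matrices, confThreshold = 0.6) {
  lapply(matrices, imputeMatrix, model = model,
         confThreshold = confThreshold)
}

#' Confidence/accuracy/yield trade-off table
#'
#' For held-out labelled predictions, tabulates at each confidence
#' threshold the fraction of cells whose confidence exceeds it and the
#' accuracy of the hard calls (\eqn{y > 0.5}) among those cells.
#'
#' @param y Predicted methylation probabilities.
#' @param labels True states (0/1).
#' @param thresholds Threshold grid (default 0.00-0.95 by 0.05; computed
#'   as exact hundredths so values like 0.6 compare cleanly).
#' @return data.frame with \code{threshold}, \code{fraction_imputed},
#'   \code{accuracy} (NA when no cell passes).
#' @export
tradeoffCurve <- function(y, labels, thresholds = seq(0L, 95L, by = 5L) / 100) {
  C <- confidence(y)
  hard <- as.integer(y > 0.5)
  out <- lapply(thresholds, function(t) {
    pass <- C > t
    data.frame(threshold = t, fraction_imputed = mean(pass),
               accuracy = if (any(pass)) mean(hard[pass] == labels[pass])
                          else NA_real_)
  })
  do.call(rbind, out)
}

#' Fully covered bin counts before and after imputation
#'
#' A bin is fully covered when it holds at least \code{minReads} complete
#' (informative) reads. Imputation can only add complete reads, so the
#' after count is never smaller.
#'
#' @param before,after Coverage data.frames over the same bin universe
#'   (from [coverageTable()]) or lists of [BinMatrix-class].
#' @param minReads Complete-read threshold (default 10).
#' @return List with \code{n_before}, \code{n_after},
#'   \code{percent_gain} (NA with a warning when \code{n_before} is 0).
#' @export
coverageGain <- function(before, after, minReads = 10L) {
  toCount <- function(x) {
    if (is.data.frame(x)) sum(x$n_informative_reads >= minReads)
    else sum(vapply(x, function(b) sum(informativeRows(b)),
                    integer(1)) >= minReads)
  }
  nb <- toCount(before); na_ <- toCount(after)
  pct <- if (nb == 0L) {
    warning("no fully covered bins before imputation; percent gain undefined")
    NA_real_
  } else 100 * (na_ - nb) / nb
  list(n_before = nb, n_after = na_, percent_gain = pct)
}
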