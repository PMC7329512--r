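miniReport <- function(binStarts, patterns, counts, chrom = "chrT") {
  df <- data.frame(chrom = chrom, bin_start = binStarts,
                   bin_end = binStarts + 100L, pattern = patterns,
                   count_A = counts, count_B = NA_integer_,
                   specificity = "single_library", class_A = "major",
                   class_B = NA_character_, bin_total_A = sum(counts),
                   bin_total_B = NA_integer_, stringsAsFactors = FALSE)
  methods::new("ClusterReport", clusters = S4Vectors::DataFrame(df),
               params = list(mode = "one-library", libraries = "mix",
                             min_reads = 10L, min_cluster_size = 4L,
                             seed = NULL, equalize = FALSE),
               nBinsProcessed = length(unique(binStarts)),
               nBinsSkipped = 0L)
}

test_that("feature tables tally (bin, pattern) read counts per mixture", {
  r1 <- miniReport(0L, "11", 7L)
  r2 <- miniReport(c(0L, 100L), c("11", "00"), c(3L, 5L))
  tab <- buildFeatureTable(list(m1 = r1, m2 = r2))
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(unname(tab["m1", ]), c(7, 0))
  expect_equal(unname(tab["m2", ]), c(3, 5))

  dmr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(101, 200))
  tab2 <- buildFeatureTable(list(m1 = r1, m2 = r2), dmr = dmr)
  expect_equal(ncol(tab2), 1L)
  expect_false(any(grepl("100-200", colnames(tab2))))

  # random reports equal a brute-force nested tally
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    reps <- lapply(seq_len(n), function(i) {
      k <- sample(2:8, 1)
      miniReport(sample(seq(0L, 900L, 100L), k),
                 replicate(k, paste(sample(0:1, 2, TRUE), collapse = "")),
                 sample(4:20, k, replace = TRUE))
    })
    names(reps) <- paste0("s", seq_len(n))
    tab <- buildFeatureTable(reps)
    for (i in seq_len(n)) {
      cl <- as.data.frame(clusters(reps[[i]]))
      for (j in seq_len(nrow(cl))) {
        key <- paste0(cl$chrom[j], ":", cl$bin_start[j], "-",
                      cl$bin_end[j], "|", cl$pattern[j])
        expect_equal(unname(tab[i, key]), sum(cl$count_A[
          paste0(cl$bin_start, cl$pattern) ==
            paste0(cl$bin_start[j], cl$pattern[j])]))
      }
    }
  }
})

test_that("malformed BED input is fatal with the offending line", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.bed")
  writeLines(c("chrT\t0\t100", "chrT\toops"), bad)
  expect_error(readBED(bad), "line 2")
})

test_that("feature alignment restricts, reorders and zero-fills columns", {
  train <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("f1", "f2", "f3")))
  test1 <- matrix(7:10, 2, 2, dimnames = list(c("x", "y"), c("g1", "g2")))
  al <- alignFeatures(train, test1)
  expect_equal(colnames(al), colnames(train))
  expect_true(all(al == 0))

  expect_equal(alignFeatures(train, train), train, ignore_attr = TRUE)
  # idempotence
  expect_equal(alignFeatures(train, alignFeatures(train, test1)),
               alignFeatures(train, test1), ignore_attr = TRUE)

  test2 <- matrix(1:4, 2, 2, dimnames = list(NULL, c("f3", "f1")))
  al2 <- alignFeatures(train, test2)
  expect_equal(unname(al2[, "f1"]), c(3, 4))
  expect_equal(unname(al2[, "f2"]), c(0, 0))
  expect_equal(unname(al2[, "f3"]), c(1, 2))
})

test_that("principal-components regression recovers a linear identity", {
  set.seed(72)
  p <- rep(seq(0.1, 0.9, 0.1), 4)
  tab <- cbind(lin = 100 * p, noise1 = 5, noise2 = 5)
  rownames(tab) <- sprintf("s%02d", seq_along(p))
  fit <- fitProportionModel(tab, p, nComponents = 2, seed = 73)
  expect_lt(fit@cvRMSE, 1e-6)
  expect_error(fitProportionModel(tab[1:3, ], p[1:3], nComponents = 20),
               "lower nComponents")

  # duplicating a feature column leaves predictions unchanged
  tab2 <- cbind(tab, lin2 = tab[, "lin"])
  fit2 <- fitProportionModel(tab2, p, nComponents = 2, seed = 73)
  pr1 <- predictProportions(fit, tab)
  pr2 <- predictProportions(fit2, tab2)
  expect_equal(pr1, pr2, tolerance = 1e-6)

  # predictions are clipped and require aligned columns
  expect_true(all(pr1 >= 0 & pr1 <= 1))
  expect_error(predictProportions(fit, tab2), "alignFeatures")
})

test_that("gene selection flags two-sigma log-fold-change outliers", {
  # 98 genes with delta 0 plus one at +10 and one at -10
  fpkmB <- rep(3, 100)
  fpkmA <- rep(3, 100)
  fpkmA[99] <- (fpkmB[99] + 1) * 2^10 - 1   # delta +10
  fpkmB[100] <- 1023; fpkmA[100] <- 0       # delta -10
  sel <- selectDifferentialGenes(fpkmA, fpkmB)
  expect_equal(which(sel$selected), c(99L, 100L))
  expect_equal(sel$label[99:100], c("A", "B"))
  # hand computation: sd = sqrt((100+100)/99), threshold ~2.84
  expect_equal(sd(sel$delta_log2), sqrt(200 / 99))

  expect_false(any(selectDifferentialGenes(rep(2, 10), rep(2, 10))$selected))
  expect_error(selectDifferentialGenes(c(-1, 2), c(1, 1)), "non-negative")

  set.seed(74)
  lfc <- rnorm(2000)
  fA <- pmax(2^lfc * 4 - 1, 0)
  selS <- selectDifferentialGenes(fA, rep(3, 2000))
  tabl <- table(selS$label[selS$selected])
  expect_gt(min(tabl) / max(tabl), 0.4)   # symmetric deltas, balanced labels
})

test_that("promoter features average CpGs and collect window clusters", {
  genes <- data.frame(gene_id = "g1", chrom = "chrT", tss = 10000L,
                      strand = "+", stringsAsFactors = FALSE)
  mkcov <- function(meths, pos0) data.frame(
    chrom = "chrT", start = pos0 + 1L, end = pos0 + 1L, meth_pct = meths,
    count_m = 5L, count_u = 5L, stringsAsFactors = FALSE)
  cov <- mkcov(c(20, 40, 90), c(8000L, 10000L, 12000L))
  repdf <- data.frame(chrom = "chrT", bin_start = c(9000L, 13000L),
                      bin_end = c(9100L, 13100L), pattern = c("11", "00"),
                      count_A = c(6L, 9L), count_B = c(0L, 2L),
                      specificity = c("A_only", "shared"),
                      class_A = "major", class_B = c("absent", "minor"),
                      bin_total_A = 10L, bin_total_B = 10L)
  pf <- buildPromoterFeatures(genes, makeReport(repdf), cov, cov,
                              includeDeciles = TRUE)
  f <- pf$features
  expect_equal(unname(f[1, "mean_meth_A"]), 50)
  # deciles: 20 -> bin 3, 40 -> bin 5, 90 -> bin 10 (closed top range)
  expect_equal(unname(f[1, c("decile_A_3", "decile_A_5", "decile_A_10")]),
               rep(1 / 3, 3))
  expect_equal(sum(f[1, paste0("decile_A_", 1:10)]), 1)
  expect_equal(unname(f[1, "11|A_only"]), 6)
  # the 13000-13100 bin starts exactly at TSS+3000: excluded (half-open)
  expect_false("00|shared" %in% colnames(f))

  # no clusters near the promoter -> zero cluster features
  genes2 <- data.frame(gene_id = "g2", chrom = "chrT", tss = 50000L,
                       strand = "+", stringsAsFactors = FALSE)
  cov2 <- mkcov(c(10, 30), c(49000L, 50500L))
  pf2 <- buildPromoterFeatures(genes2, makeReport(repdf), cov2, cov2)
  expect_equal(ncol(pf2$features), 2L)

  # promoters without CpG coverage are dropped and counted
  genes3 <- rbind(genes, genes2)
  pf3 <- buildPromoterFeatures(genes3, makeReport(repdf), cov, cov)
  expect_equal(pf3$genes, "g1")
  expect_equal(pf3$nDropped, 1L)
})

test_that("decile vectors are probability vectors consistent with the mean", {
  set.seed(75)
  genes <- data.frame(gene_id = sprintf("g%d", 1:20), chrom = "chrT",
                      tss = seq(10000L, by = 10000L, length.out = 20),
                      strand = "+", stringsAsFactors = FALSE)
  cov <- do.call(rbind, lapply(seq_len(20), function(i) {
    pos0 <- genes$tss[i] + sample(-2999:2998, 30)
    data.frame(chrom = "chrT", start = pos0 + 1L, end = pos0 + 1L,
               meth_pct = runif(30, 0, 100), count_m = 5L, count_u = 5L)
  }))
  emptyRep <- makeReport(data.frame(chrom = "chrX", bin_start = 0L,
                                    bin_end = 100L, pattern = "11",
                                    count_A = 5L, count_B = 5L,
                                    specificity = "shared", class_A = "major",
                                    class_B = "major", bin_total_A = 10L,
                                    bin_total_B = 10L))
  pf <- buildPromoterFeatures(genes, emptyRep, cov, cov,
                              includeDeciles = TRUE)
  dec <- pf$features[, paste0("decile_A_", 1:10)]
  expect_equal(unname(rowSums(dec)), rep(1, nrow(dec)))
  mids <- seq(5, 95, by = 10)
  approxMean <- as.vector(dec %*% mids)
  expect_true(all(abs(approxMean - pf$features[, "mean_meth_A"]) <= 5))
})

test_that("expression forests separate separable labels and reject one class", {
  set.seed(76)
  n <- 200
  x <- cbind(a = runif(n), b = runif(n))
  y <- ifelse(x[, "a"] > 0.5, "A", "B")
  x[, "a"] <- ifelse(y == "A", runif(n, 0.6, 1), runif(n, 0, 0.4))
  res <- trainExpressionModel(x, y, nSplits = 10,
                              grid = list(num_trees = 50, max_depth = 10),
                              cvFolds = 5, seed = 77)
  expect_equal(mean(res$auc), 1.0)
  expect_error(trainExpressionModel(x, rep("A", n)), "two classes")

  # nested mode returns one AUC per outer fold
  resN <- trainExpressionModel(x, y, nested = TRUE, nestedFolds = 5,
                               grid = list(num_trees = 50, max_depth = 10),
                               cvFolds = 3, seed = 78)
  expect_length(resN$auc, 5L)
  expect_gt(mean(resN$auc), 0.95)
})
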