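test_that("informative-read counting matches a brute-force row scan", {
  bin <- BinSpec("chrT", 0L, 100L, c(10L, 20L))
  m <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 0L), c(1L, -1L))
  bm <- BinMatrix(bin, m)
  expect_equal(computeBinCoverage(bm)$n_informative_reads, 3L)
  expect_true(computeBinCoverage(bm)$eligible)

  empty <- BinMatrix(bin, matrix(integer(0), 0, 2), labels = character(0),
                     readIds = character(0))
  expect_equal(computeBinCoverage(empty)$n_informative_reads, 0L)

  d1 <- BinMatrix(BinSpec("chrT", 0L, 100L, 10L), matrix(1L, 3, 1))
  expect_false(computeBinCoverage(d1)$eligible)

  set.seed(31)
  for (i in 1:25) {
    bm <- randomBinMatrix(50, 3)
    oracle <- sum(apply(callMatrix(bm), 1, function(r) all(r != -1L)))
    expect_equal(computeBinCoverage(bm)$n_informative_reads, oracle)
  }
})

test_that("depth equalisation subsamples only the deeper library, reproducibly", {
  bin <- BinSpec("chrT", 0L, 100L, c(10L, 20L))
  m <- matrix(1L, 24, 2)
  bm <- BinMatrix(bin, m, labels = rep(c("A", "B"), c(14, 10)))
  eq <- equalizeDepth(bm, seed = 3)
  expect_equal(sum(readLabels(eq) == "A"), 10L)
  expect_equal(sum(readLabels(eq) == "B"), 10L)

  bal <- BinMatrix(bin, matrix(1L, 20, 2), labels = rep(c("A", "B"), 10))
  expect_identical(equalizeDepth(bal, seed = 3), bal)

  # single-library matrices pass through untouched
  single <- BinMatrix(bin, m, labels = "A")
  expect_identical(equalizeDepth(single, seed = 3), single)

  eq2 <- equalizeDepth(bm, seed = 3)
  expect_identical(readIds(eq), readIds(eq2))
  # non-informative rows are never dropped
  m2 <- m; m2[1, 2] <- -1L
  bm2 <- BinMatrix(bin, m2, labels = rep(c("A", "B"), c(14, 10)))
  eq3 <- equalizeDepth(bm2, seed = 4)
  expect_true("read1" %in% readIds(eq3))
})

test_that("identity clustering applies the minimum-size filter and ordering", {
  bin <- BinSpec("chrT", 0L, 100L, c(10L, 20L, 30L))
  pats <- c(rep("110", 5), rep("000", 4), rep("101", 3))
  m <- do.call(rbind, lapply(strsplit(pats, ""), as.integer))
  cl <- clusterReads(BinMatrix(bin, m), minClusterSize = 4)
  expect_equal(cl$pattern, c("110", "000"))
  expect_equal(cl$total, c(5L, 4L))

  cl10 <- clusterReads(BinMatrix(bin, matrix(1L, 10, 3)))
  expect_equal(nrow(cl10), 1L)
  expect_equal(cl10$total, 10L)
})

test_that("clustering equals the brute-force pattern tally on random matrices", {
  set.seed(41)
  for (i in 1:200) {
    bm <- randomBinMatrix(sample(5:40, 1), sample(2:4, 1),
                          labels = c("A", "B"))
    got <- clusterReads(bm, minClusterSize = 4)
    oracle <- bruteTally(bm, minClusterSize = 4)
    expect_equal(got$pattern, oracle$pattern)
    expect_equal(got$total, oracle$total)
    if (nrow(got)) {
      expect_equal(got$count_A, oracle$count_A)
      expect_equal(got$count_B, oracle$count_B)
    }
  }
})

test_that("cluster counts and labels are invariant to read order", {
  set.seed(43)
  bm <- randomBinMatrix(30, 3, labels = c("A", "B"), missingFrac = 0.1)
  perm <- sample(nrow(callMatrix(bm)))
  shuf <- BinMatrix(binOf(bm), callMatrix(bm)[perm, ],
                    labels = readLabels(bm)[perm],
                    readIds = readIds(bm)[perm])
  expect_equal(clusterReads(bm), clusterReads(shuf),
               ignore_attr = TRUE)
})

test_that("specificity labels follow the zero-count rule", {
  bin <- BinSpec("chrT", 0L, 100L, c(10L, 20L))
  mk <- function(nA, nB) {
    m <- matrix(1L, nA + nB, 2)
    clusterReads(BinMatrix(bin, m, labels = rep(c("A", "B"), c(nA, nB))),
                 libraries = c("A", "B"))
  }
  expect_equal(labelSpecificity(mk(5, 0))$specificity, "A_only")
  expect_equal(labelSpecificity(mk(3, 2))$specificity, "shared")
  expect_equal(labelSpecificity(mk(0, 7))$specificity, "B_only")
  one <- clusterReads(BinMatrix(bin, matrix(1L, 5, 2), labels = "A"))
  expect_equal(labelSpecificity(one)$specificity, "single_library")
})

test_that("major/minor classification uses the >= 50% boundary", {
  bin <- BinSpec("chrT", 0L, 100L, c(10L, 20L))
  classify <- function(n) {
    pats <- c(rep("11", n), rep("00", 10 - n))
    m <- do.call(rbind, lapply(strsplit(pats, ""), as.integer))
    cl <- clusterReads(BinMatrix(bin, m, labels = "A"), libraries = "A")
    classifyMajorMinor(cl, c(A = 10L))
  }
  expect_equal(classify(6)$class_A[1], "major")
  expect_equal(classify(5)[classify(5)$pattern == "11", "class_A"], "major")
  expect_equal(classify(4)[classify(4)$pattern == "11", "class_A"], "minor")
  # zero total with positive count is inconsistent
  cl <- clusterReads(BinMatrix(bin, matrix(1L, 5, 2), labels = "A"),
                     libraries = "A")
  expect_error(classifyMajorMinor(cl, c(A = 0L)), "zero bin total")
})

test_that("per-bin cluster counts never exceed equalised bin totals", {
  cfg <- simulationConfig(nBins = 40, depth = 20, seed = 9)
  pr <- simulateProfiles(cfg)
  sa <- simulateReads(pr$profileA, cfg, seed = 10, label = "A")
  sb <- simulateReads(pr$profileB, cfg, seed = 11, label = "B")
  rep2 <- clusterBins(mergeLibraries(sa$matrices, sb$matrices),
                      minReads = 10, seed = 12)
  cl <- as.data.frame(clusters(rep2))
  for (bs in unique(cl$bin_start)) {
    sub <- cl[cl$bin_start == bs, ]
    expect_lte(sum(sub$count_A), sub$bin_total_A[1])
    expect_lte(sum(sub$count_B), sub$bin_total_B[1])
  }
})

test_that("planted cell type-specific patterns are recovered as unique clusters", {
  cfg <- simulationConfig(nBins = 600, depth = 20, fracSpecific = 0.08,
                          seed = 21)
  pr <- simulateProfiles(cfg)
  sa <- simulateReads(pr$profileA, cfg, seed = 22, label = "A")
  sb <- simulateReads(pr$profileB, cfg, seed = 23, label = "B")
  rep2 <- clusterBins(mergeLibraries(sa$matrices, sb$matrices),
                      minReads = 10, seed = 24)
  cl <- as.data.frame(clusters(rep2))
  coveredStarts <- unique(cl$bin_start)
  planted <- pr$truth[pr$truth$specific != "none" &
                        pr$truth$start %in% coveredStarts, ]
  hit <- logical(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    sub <- cl[cl$bin_start == planted$start[i], ]
    want <- if (planted$specific[i] == "A") "A_only" else "B_only"
    hit[i] <- any(sub$pattern == planted$planted_pattern[i] &
                    sub$specificity == want)
  }
  expect_gt(nrow(planted), 20)
  expect_gte(mean(hit), 0.95)
})

test_that("a library below the coverage floor empties the comparison", {
  cfgA <- simulationConfig(nBins = 15, depth = 20, seed = 13)
  cfgB <- simulationConfig(nBins = 15, depth = 3, seed = 13)
  pr <- simulateProfiles(cfgA)
  sa <- simulateReads(pr$profileA, cfgA, seed = 14, label = "A")
  sb <- simulateReads(pr$profileB, cfgB, seed = 15, label = "B")
  rep2 <- clusterBins(mergeLibraries(sa$matrices, sb$matrices),
                      minReads = 10, seed = 16)
  expect_equal(nrow(clusters(rep2)), 0L)
  expect_gt(nBinsSkipped(rep2), 0L)
  expect_error(summarizeUniqueFraction(rep2), "empty")
})

test_that("unique-cluster fractions are plain proportions of the report", {
  df <- data.frame(chrom = "chrT", bin_start = rep(0L, 20), bin_end = 100L,
                   pattern = sprintf("%02d", 1:20),
                   count_A = c(rep(5L, 2), rep(0L, 2), rep(3L, 16)),
                   count_B = c(rep(0L, 2), rep(5L, 2), rep(3L, 16)),
                   specificity = c("A_only", "A_only", "B_only", "B_only",
                                   rep("shared", 16)),
                   class_A = "minor", class_B = "minor",
                   bin_total_A = 60L, bin_total_B = 60L)
  r <- makeReport(df)
  expect_equal(summarizeUniqueFraction(r), c(A = 0.1, B = 0.1))
  dfAll <- df; dfAll$specificity <- "shared"
  expect_equal(summarizeUniqueFraction(makeReport(dfAll)), c(A = 0, B = 0))
})

test_that("full BAM comparison runs and reports survive a disk round trip", {
  cfg <- simulationConfig(nBins = 25, depth = 20, seed = 17)
  pr <- simulateProfiles(cfg)
  sa <- simulateReads(pr$profileA, cfg, seed = 18, label = "A")
  sb <- simulateReads(pr$profileB, cfg, seed = 19, label = "B")
  dir <- withr::local_tempdir()
  bamA <- file.path(dir, "A.bam"); bamB <- file.path(dir, "B.bam")
  writeSyntheticBam(sa, pr$profileA, bamA)
  writeSyntheticBam(sb, pr$profileB, bamB)
  rep2 <- compareLibraries(bamA, bamB, pr$profileA$bins, minReads = 10,
                           seed = 20, labels = c("A", "B"))
  expect_s4_class(rep2, "ClusterReport")
  expect_gt(nrow(clusters(rep2)), 0L)
  expect_error(compareLibraries(file.path(dir, "absent.bam"), bamB,
                                pr$profileA$bins), "absent")
  f <- file.path(dir, "report.tsv")
  writeClusterReport(rep2, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- readClusterReport(f)
  expect_equal(as.data.frame(clusters(back)),
               as.data.frame(clusters(rep2)))
  expect_equal(reportParams(back)$min_reads, 10L)
})
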