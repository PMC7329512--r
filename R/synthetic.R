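#' Configuration for the synthetic WGBS generator
#'
#' Bundles the generative assumptions the analysis stack targets:
#' two cell types share most bins' epiallele (read-pattern)
#' distributions, a small fraction of bins (default 8\%) carry a pattern
#' planted in exactly one cell type, shared distributions are biased
#' towards the fully methylated pattern, and reads miss bin CpGs through
#' prefix/suffix truncation as shotgun reads partially overlap a bin.
#'
#' @param nBins Number of 100-bp bins.
#' @param densityProbs Named probabilities of CpG densities 2-5.
#' @param fracSpecific Fraction of bins with a cell type-specific planted
#'   pattern (default 0.08).
#' @param depth Reads per bin per library (default 20).
#' @param missingness Per-read probability of truncation hiding a prefix
#'   or suffix of the bin's CpGs (default 0.3).
#' @param sharedMethBias Probability mass placed on the fully methylated
#'   pattern in shared distributions (default 0.55).
#' @param plantedProb Mass of the planted pattern in the cell type that
#'   carries it (>= 0.5; default 0.6).
#' @param fracDMR Fraction of bins with a conventional mean-methylation
#'   difference (a planted DMR; default 0).
#' @param chrom Contig name.
#' @param seed Integer seed.
#' @return A list of class \code{"epipattern_sim_config"}.
#' @export
simulationConfig <- function(nBins = 2000L,
                             densityProbs = c(`2` = 0.4, `3` = 0.3,
                                              `4` = 0.2, `5` = 0.1),
                             fracSpecific = 0.08, depth = 20L,
                             missingness = 0.3, sharedMethBias = 0.55,
                             plantedProb = 0.6, fracDMR = 0,
                             chrom = "chrS", seed = 1L) {
  stopifnot(depth >= 1L, fracSpecific >= 0, fracSpecific <= 1,
            missingness >= 0, missingness <= 1, plantedProb >= 0.5,
            abs(sum(densityProbs) - 1) < 1e-8)
  structure(list(nBins = as.integer(nBins), densityProbs = densityProbs,
                 fracSpecific = fracSpecific, depth = as.integer(depth),
                 missingness = missingness,
                 sharedMethBias = sharedMethBias,
                 plantedProb = plantedProb, fracDMR = fracDMR,
                 chrom = chrom, seed = as.integer(seed)),
            class = "epipattern_sim_config")
}

.allPatterns <- function(d) {
  apply(expand.grid(rep(list(0:1), d))[, d:1, drop = FALSE], 1L,
        paste0, collapse = "")
}

#' Simulate per-bin epiallele distributions for two cell types
#'
#' Shared bins receive identical categorical pattern distributions in
#' both cell types, with the modal mass on the fully methylated pattern.
#' Cell type-specific bins plant a pattern with probability
#' \code{plantedProb} in exactly one cell type and zero in the other.
#' Optional DMR-style bins differ in mean methylation instead (mass
#' shifted towards all-methylated in A and all-unmethylated in B).
#'
#' @param config From [simulationConfig()].
#' @return List with \code{profileA}, \code{profileB} (each: \code{bins},
#'   a list of [BinSpec-class]; \code{dist}, per-bin lists with
#'   \code{patterns} and \code{probs}) and \code{truth} (data.frame of
#'   planted bins, patterns, sides and DMR flags).
#' @export
simulateProfiles <- function(config) {
  .withSeed(config$seed, {
    n <- config$nBins
    dvals <- as.integer(names(config$densityProbs))
    ds <- sample(dvals, n, replace = TRUE, prob = config$densityProbs)
    specific <- stats::runif(n) < config$fracSpecific
    side <- ifelse(specific, sample(c("A", "B"), n, replace = TRUE), "none")
    dmr <- stats::runif(n) < config$fracDMR & !specific
    bins <- vector("list", n)
    distA <- vector("list", n); distB <- vector("list", n)
    planted <- character(n)
    for (i in seq_len(n)) {
      start <- (i - 1L) * 100L
      d <- ds[i]
      pos <- start + sort(sample(seq(10L, 86L, by = 4L), d))
      bins[[i]] <- BinSpec(config$chrom, start, start + 100L, pos)
      pats <- .allPatterns(d)
      allOne <- paste(rep("1", d), collapse = "")
      allZero <- paste(rep("0", d), collapse = "")
      others <- setdiff(pats, allOne)
      reserve <- sample(others, 1L)
      pool <- setdiff(others, reserve)
      ## low-entropy shared distribution: the fully methylated mode, one
      ## major alternative epiallele, and a little rare-pattern mass
      ## (sub-cluster-threshold stochastic reads)
      alt <- sample(pool, 1L)
      rare <- setdiff(pool, alt)
      nr <- min(2L, length(rare))
      rare <- if (nr > 0L) sample(rare, nr) else character(0)
      rareMass <- 0.02
      altMass <- 1 - config$sharedMethBias - rareMass
      base <- c(config$sharedMethBias, altMass,
                rep(rareMass / max(nr, 1L), nr))
      basePat <- c(allOne, alt, rare)
      if (dmr[i]) {
        k <- length(basePat) - 1L
        pA <- c(0.8, rep(0.2 / k, k))
        patB <- c(allZero, setdiff(basePat, allZero)[seq_len(k)])
        distA[[i]] <- list(patterns = basePat, probs = pA)
        distB[[i]] <- list(patterns = patB, probs = pA)
        planted[i] <- ""
      } else if (side[i] == "none") {
        distA[[i]] <- list(patterns = basePat, probs = base)
        distB[[i]] <- distA[[i]]
        planted[i] <- ""
      } else {
        ## the planted epiallele stands in for the alternative pattern:
        ## the carrying cell type mixes it with the methylated mode, the
        ## other cell type keeps the mode (plus rare stochastic reads)
        baseSpec <- c(1 - rareMass, rep(rareMass / max(nr, 1L), nr))
        baseSpecPat <- c(allOne, rare)
        spec <- list(patterns = c(reserve, baseSpecPat),
                     probs = c(config$plantedProb,
                               (1 - config$plantedProb) * baseSpec))
        shared <- list(patterns = baseSpecPat, probs = baseSpec)
        if (side[i] == "A") { distA[[i]] <- spec; distB[[i]] <- shared }
        else { distA[[i]] <- shared; distB[[i]] <- spec }
        planted[i] <- reserve
      }
    }
    truth <- data.frame(
      bin = seq_len(n), chrom = config$chrom,
      start = vapply(bins, binStart, integer(1)),
      end = vapply(bins, binEnd, integer(1)),
      density = ds, specific = side, planted_pattern = planted,
      dmr = dmr, stringsAsFactors = FALSE)
    list(profileA = list(bins = bins, dist = distA),
         profileB = list(bins = bins, dist = distB),
         truth = truth)
  })
}

#' Simulate reads for one cell type profile
#'
#' Per bin, \code{depth} reads are drawn i.i.d. from the bin's pattern
#' distribution; truncation missingness then hides a random prefix or
#' suffix of each affected read's CpGs (with \code{missingness = 1} every
#' read is truncated, so no read is fully informative). Each read is
#' assigned a strand for BAM export.
#'
#' @param profile \code{profileA}/\code{profileB} from
#'   [simulateProfiles()].
#' @param config From [simulationConfig()].
#' @param seed Integer seed.
#' @param label Library label on every read.
#' @return List with \code{matrices} (list of [BinMatrix-class]),
#'   \code{strand} (per-bin logical vectors, TRUE = reverse) and
#'   \code{truth} (per-bin matrices of the full, untruncated patterns).
#' @export
simulateReads <- function(profile, config, seed = config$seed,
                          label = "A") {
  .withSeed(seed, {
    n <- length(profile$bins)
    mats <- vector("list", n)
    strands <- vector("list", n)
    truthMats <- vector("list", n)
    for (i in seq_len(n)) {
      bin <- profile$bins[[i]]
      d <- binDensity(bin)
      dist <- profile$dist[[i]]
      depth <- max(2L, stats::rpois(1L, config$depth))
      pat <- sample(dist$patterns, depth, replace = TRUE,
                    prob = dist$probs)
      full <- matrix(as.integer(unlist(strsplit(pat, "", fixed = TRUE))),
                     nrow = depth, ncol = d, byrow = TRUE)
      m <- full
      if (config$missingness > 0 && d >= 2L) {
        trunc <- stats::runif(depth) < config$missingness
        for (r in which(trunc)) {
          k <- sample.int(d - 1L, 1L)
          if (stats::runif(1) < 0.5) m[r, seq_len(k)] <- -1L
          else m[r, (d - k + 1L):d] <- -1L
        }
      }
      ids <- sprintf("%s_b%05d_r%03d", label, i, seq_len(depth))
      mats[[i]] <- BinMatrix(bin, m, labels = label, readIds = ids)
      strands[[i]] <- stats::runif(depth) < 0.5
      truthMats[[i]] <- full
    }
    list(matrices = mats, strand = strands, truth = truthMats)
  })
}

#' Simulate an in silico mixture of two cell types
#'
#' Each read is drawn from cell type A with probability \code{p} and
#' from B otherwise, keeping the total depth fixed, mirroring
#' computational mixing of reads from pure libraries.
#'
#' @param profileA,profileB Profiles from [simulateProfiles()].
#' @param p Fraction of cell type A in [0, 1].
#' @param config From [simulationConfig()].
#' @param seed Integer seed.
#' @param label Library label (mixtures are single-library).
#' @return List with \code{matrices}, \code{p} and \code{sourceCounts}
#'   (per-bin number of reads drawn from A).
#' @export
simulateMixture <- function(profileA, profileB, p, config,
                            seed = config$seed, label = "mix") {
  stopifnot(p >= 0, p <= 1)
  .withSeed(seed, {
    n <- length(profileA$bins)
    mats <- vector("list", n)
    srcA <- integer(n)
    for (i in seq_len(n)) {
      bin <- profileA$bins[[i]]
      d <- binDensity(bin)
      depth <- max(2L, stats::rpois(1L, config$depth))
      fromA <- stats::runif(depth) < p
      srcA[i] <- sum(fromA)
      pat <- character(depth)
      if (any(fromA))
        pat[fromA] <- sample(profileA$dist[[i]]$patterns, sum(fromA),
                             replace = TRUE,
                             prob = profileA$dist[[i]]$probs)
      if (any(!fromA))
        pat[!fromA] <- sample(profileB$dist[[i]]$patterns, sum(!fromA),
                              replace = TRUE,
                              prob = profileB$dist[[i]]$probs)
      m <- matrix(as.integer(unlist(strsplit(pat, "", fixed = TRUE))),
                  nrow = depth, ncol = d, byrow = TRUE)
      if (config$missingness > 0 && d >= 2L) {
        trunc <- stats::runif(depth) < config$missingness
        for (r in which(trunc)) {
          k <- sample.int(d - 1L, 1L)
          if (stats::runif(1) < 0.5) m[r, seq_len(k)] <- -1L
          else m[r, (d - k + 1L):d] <- -1L
        }
      }
      ids <- sprintf("%s_b%05d_r%03d", label, i, seq_len(depth))
      mats[[i]] <- BinMatrix(bin, m, labels = label, readIds = ids)
    }
    list(matrices = mats, p = p, sourceCounts = srcA)
  })
}

#' Simulate i.i.d. Bernoulli bins with no pattern structure
#'
#' Each bin's cells are independent Bernoulli draws with a per-column
#' methylation rate drawn uniformly; the column mean is then the optimal
#' predictor of a missing cell, providing the null scenario for
#' imputation benchmarking.
#'
#' @param nBins Number of bins.
#' @param d CpG density of every bin.
#' @param depth Reads per bin.
#' @param missingness Per-read truncation probability.
#' @param seed Integer seed.
#' @param chrom Contig name.
#' @return List of [BinMatrix-class].
#' @export
simulateIIDBins <- function(nBins, d = 3L, depth = 20L,
                            missingness = 0.3, seed = 1L,
                            chrom = "chrN") {
  .withSeed(seed, {
    mats <- vector("list", nBins)
    for (i in seq_len(nBins)) {
      start <- (i - 1L) * 100L
      pos <- start + sort(sample(seq(10L, 86L, by = 4L), d))
      bin <- BinSpec(chrom, start, start + 100L, pos)
      q <- stats::runif(d, 0.1, 0.9)
      di <- max(2L, stats::rpois(1L, depth))
      m <- matrix(as.integer(stats::runif(di * d) <
                               rep(q, each = di)), di, d)
      if (missingness > 0) {
        trunc <- stats::runif(di) < missingness
        for (r in which(trunc)) {
          k <- sample.int(d - 1L, 1L)
          if (stats::runif(1) < 0.5) m[r, seq_len(k)] <- -1L
          else m[r, (d - k + 1L):d] <- -1L
        }
      }
      mats[[i]] <- BinMatrix(bin, m, labels = "N",
                             readIds = sprintf("N_b%05d_r%03d", i,
                                               seq_len(di)))
    }
    mats
  })
}

## ---- BAM export --------------------------------------------------------

#' Build the toy reference sequence implied by a profile
#'
#' An A/T background (so no spurious CpG arises) with "CG" placed at
#' every bin CpG position.
#'
#' @param profile A profile from [simulateProfiles()].
#' @param seed Seed for the background bases.
#' @return A named [Biostrings::DNAStringSet-class] of length 1.
#' @export
syntheticReference <- function(profile, seed = 1L) {
  bins <- profile$bins
  len <- max(vapply(bins, binEnd, integer(1)))
  chrom <- binChrom(bins[[1]])
  base <- .withSeed(seed, sample(c("A", "T"), len, replace = TRUE))
  for (b in bins) for (p in cpgPositions(b)) {
    base[p + 1L] <- "C"; base[p + 2L] <- "G"
  }
  out <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(out) <- chrom
  out
}

#' Write simulated reads as an indexed BAM with call-string tags
#'
#' Encodes each simulated read segment as a SAM record over the toy
#' reference: the aligned sequence carries C/T (forward) or G/A
#' (reverse) at CpG sites according to the methylation state, and the
#' XM-style tag carries Z/z at the CpG offsets (on the G for
#' reverse-strand reads, as bisulfite aligners report). The SAM text is
#' converted to a coordinate-sorted, indexed BAM.
#'
#' @param sim Output of [simulateReads()] or [simulateMixture()].
#' @param profile The profile the reads were drawn from.
#' @param bamPath Output BAM path (without requiring the .bam suffix).
#' @param fastaPath Optional path to also write the toy reference FASTA.
#' @param tag Tag name for the call string (default "XM").
#' @return The BAM path, invisibly.
#' @export
writeSyntheticBam <- function(sim, profile, bamPath, fastaPath = NULL,
                              tag = "XM") {
  ref <- syntheticReference(profile)
  if (!is.null(fastaPath))
    Biostrings::writeXStringSet(ref, fastaPath)
  chrom <- names(ref)
  refChars <- strsplit(as.character(ref[[1]]), "")[[1]]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", chrom, "\tLN:", length(refChars)))
  recs <- character(0)
  mats <- sim$matrices
  strands <- sim$strand
  for (i in seq_along(mats)) {
    x <- mats[[i]]
    m <- callMatrix(x)
    if (nrow(m) == 0L) next
    pos <- cpgPositions(x)
    rev <- if (is.null(strands)) rep(FALSE, nrow(m)) else strands[[i]]
    binRecs <- character(nrow(m))
    starts <- integer(nrow(m))
    for (r in seq_len(nrow(m))) {
      cov <- which(m[r, ] != -1L)
      p1 <- pos[cov[1]]                      # 0-based first C
      p2 <- pos[cov[length(cov)]] + 1L       # 0-based last G
      L <- p2 - p1 + 1L
      seqv <- refChars[(p1 + 1L):(p2 + 1L)]
      xm <- rep(".", L)
      for (ci in cov) {
        offC <- pos[ci] - p1 + 1L
        meth <- m[r, ci] == 1L
        if (rev[r]) {
          xm[offC + 1L] <- if (meth) "Z" else "z"
          seqv[offC + 1L] <- if (meth) "G" else "A"
        } else {
          xm[offC] <- if (meth) "Z" else "z"
          seqv[offC] <- if (meth) "C" else "T"
        }
      }
      starts[r] <- p1 + 1L
      binRecs[r] <- paste(readIds(x)[r], if (rev[r]) 16L else 0L, chrom,
                          p1 + 1L, 42L, paste0(L, "M"), "*", 0L, 0L,
                          paste(seqv, collapse = ""),
                          paste(rep("I", L), collapse = ""),
                          paste0(tag, ":Z:", paste(xm, collapse = "")),
                          sep = "\t")
    }
    recs <- c(recs, binRecs[order(starts, readIds(x))])
  }
  samPath <- paste0(sub("\\.bam$", "", bamPath), ".sam")
  writeLines(c(header, recs), samPath)
  dest <- Rsamtools::asBam(samPath, sub("\\.bam$", "", bamPath),
                           overwrite = TRUE, indexDestination = TRUE)
  unlink(samPath)
  invisible(dest)
}

## ---- linked expression data -------------------------------------------

#' Simulate genes with promoter cluster features linked to expression
#'
#' Generates a balanced set of genes whose binary label (which cell type
#' expresses the gene more highly) is carried, with strength
#' \code{effectSize}, by (i) a mean promoter methylation difference
#' between the cell types and (ii) an excess of label-concordant cell
#' type-specific promoter clusters. A fraction of genes carry a
#' \emph{major} specific cluster (holding at least half of its
#' library's bin reads) with a stronger read count. With
#' \code{effectSize = 0} every feature is independent of the label.
#' FPKM values are generated so that the label equals the sign of
#' \eqn{\Delta\log_2} FPKM.
#'
#' @param nGenes Number of genes.
#' @param effectSize Strength of the label-feature link (default 1; 0 =
#'   null).
#' @param fracMajor Fraction of genes whose specific promoter cluster is
#'   major (default 0.3).
#' @param seed Integer seed.
#' @param chrom Contig name.
#' @return List with \code{genes} (gene table incl. FPKM columns),
#'   \code{labels}, \code{report} (a two-library [ClusterReport-class]
#'   over promoter bins), \code{covA}, \code{covB} (per-CpG coverage
#'   tables), and \code{hasMajor} (logical per gene).
#' @export
simulateExpression <- function(nGenes = 500L, effectSize = 1,
                               fracMajor = 0.3, seed = 1L,
                               chrom = "chrE") {
  .withSeed(seed, {
    tss <- 5000L + (seq_len(nGenes) - 1L) * 10000L
    strand <- rep(c("+", "-"), length.out = nGenes)
    lab <- sample(rep(c("A", "B"), length.out = nGenes))
    sgn <- ifelse(lab == "A", 1, -1)
    hasMajor <- stats::runif(nGenes) < fracMajor
    ## FPKM: label = sign of delta-log2 by construction
    lfc <- (2 + stats::rgamma(nGenes, 2, 1)) * sgn
    fpkmB <- stats::rlnorm(nGenes, meanlog = 2, sdlog = 1)
    fpkmA <- (fpkmB + 1) * 2^lfc - 1
    fpkmA <- pmax(fpkmA, 0)
    ## promoter methylation: moderate, noisy label signal; the more
    ## highly expressed cell type gets the less methylated promoter
    mA <- stats::runif(nGenes, 25, 75)
    dm <- effectSize * sgn * stats::rnorm(nGenes, 6, 2) +
      stats::rnorm(nGenes, 0, 8)
    mB <- pmin(pmax(mA + dm, 0), 100)
    ## per-CpG coverage tables
    covRows <- function(means) {
      nC <- 15L
      do.call(rbind, lapply(seq_len(nGenes), function(i) {
        pos0 <- tss[i] - 2900L + seq(0L, by = 400L, length.out = nC)
        meth <- pmin(pmax(stats::rnorm(nC, means[i], 10), 0), 100)
        tot <- 30L
        cm <- round(tot * meth / 100)
        data.frame(chrom = chrom, start = pos0 + 1L, end = pos0 + 1L,
                   meth_pct = meth, count_m = cm, count_u = tot - cm,
                   stringsAsFactors = FALSE)
      }))
    }
    covA <- covRows(mA)
    covB <- covRows(mB)
    ## promoter cluster report
    specPats <- c("0101", "1010", "0011")
    sharedPat <- "1111"
    rows <- vector("list", nGenes)
    for (i in seq_len(nGenes)) {
      binStart <- (tss[i] %/% 100L) * 100L
      own <- lab[i]; other <- if (own == "A") "B" else "A"
      lamConc <- 1 + effectSize * (if (hasMajor[i]) 14 else 4)
      lamDisc <- 1
      nconc <- stats::rpois(1, lamConc)
      ndisc <- stats::rpois(1, lamDisc)
      nshared <- stats::rpois(1, 8) + 4L
      pat <- sample(specPats, 2L)
      mk <- function(pattern, cA, cB) {
        spec <- if (cA > 0L && cB == 0L) "A_only"
                else if (cB > 0L && cA == 0L) "B_only" else "shared"
        list(pattern = pattern, count_A = cA, count_B = cB,
             specificity = spec)
      }
      entries <- list(mk(sharedPat, nshared, nshared))
      if (nconc >= 4L)
        entries <- c(entries, list(
          mk(pat[1], if (own == "A") nconc else 0L,
             if (own == "B") nconc else 0L)))
      if (ndisc >= 4L)
        entries <- c(entries, list(
          mk(pat[2], if (other == "A") ndisc else 0L,
             if (other == "B") ndisc else 0L)))
      totA <- sum(vapply(entries, function(e) e$count_A, integer(1)))
      totB <- sum(vapply(entries, function(e) e$count_B, integer(1)))
      cls <- function(cnt, tot) {
        if (cnt == 0L) "absent" else if (cnt / tot >= 0.5) "major"
        else "minor"
      }
      rows[[i]] <- do.call(rbind, lapply(entries, function(e)
        data.frame(chrom = chrom, bin_start = binStart,
                   bin_end = binStart + 100L, pattern = e$pattern,
                   count_A = e$count_A, count_B = e$count_B,
                   specificity = e$specificity,
                   class_A = cls(e$count_A, totA),
                   class_B = cls(e$count_B, totB),
                   bin_total_A = totA, bin_total_B = totB,
                   stringsAsFactors = FALSE)))
    }
    report <- new("ClusterReport",
                  clusters = S4Vectors::DataFrame(do.call(rbind, rows)),
                  params = list(mode = "two-library",
                                libraries = c("A", "B"),
                                min_reads = 10L, min_cluster_size = 4L,
                                seed = seed, equalize = TRUE),
                  nBinsProcessed = as.integer(nGenes), nBinsSkipped = 0L)
    genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(nGenes)),
                        chrom = chrom, tss = tss, strand = strand,
                        fpkm_A = fpkmA, fpkm_B = fpkmB,
                        stringsAsFactors = FALSE)
    list(genes = genes, labels = lab, report = report, covA = covA,
         covB = covB, hasMajor = hasMajor)
  })
}
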