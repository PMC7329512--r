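# epipattern

Read-level CpG methylation pattern analysis for whole genome bisulfite
sequencing (WGBS) data, in R.

Bulk WGBS reports the *average* methylation at each CpG, which blurs away
differences between the cell types that make up a tissue. But every
sequencing read comes from a single DNA molecule in a single cell, so the
ordered pattern of methylation states along a read — its *epiallele* — is
a single-cell observation hiding in bulk data. `epipattern` is for
epigenomics researchers who want to exploit that: it finds recurrent
read-level patterns, labels the ones specific to one of two compared
samples, imputes missing read-level CpG calls to raise usable coverage,
and feeds the resulting pattern counts into two downstream inferences —
cell-mixture proportion estimation and binary gene-expression prediction.

## The method in brief

* **Binning and coverage (phase 1).** Each chromosome is tiled into
  100-bp non-overlapping bins (0-based, half-open); analysis uses bins
  with ≥ 2 CpGs. A read segment is *informative* for a bin if it covers
  every CpG in it; per-bin informative-read counts are reported.
* **Clustering (phase 2).** For each bin with ≥ `minReads` (default 10)
  informative reads per library, reads are grouped by exact pattern
  identity; groups with ≥ `minClusterSize` (default 4) reads form
  clusters. Comparing two libraries (depth-equalised per bin), a cluster
  is **A_only** / **B_only** if all of its reads come from one input,
  else **shared**; within a library a cluster holding ≥ 50 % of that
  library's bin reads is **major**, otherwise **minor**.
* **Read-level imputation.** Missingness masks harvested from the
  library's own incomplete bins are overlaid on complete bins to build
  labelled training data. Each missing CpG cell is encoded (row mean,
  column mean, indices, row states, and the 2^d "read encoding"
  frequencies of complete patterns) and a per-density random forest
  predicts the methylation probability *y*. Calls with confidence
  C = |2(y − 0.5)| above a gate (default 0.6) are imputed; observed
  cells are never touched.
* **Mixture deconvolution.** Cluster read counts per (bin, pattern),
  with DMR-overlapping bins excluded, are projected on the top 20
  principal components; a multivariate linear regression predicts the
  mixture proportion.
* **Expression prediction.** For ± 2 SD Δlog2(FPKM+1) outlier genes, a
  random forest predicts which cell type expresses the gene more highly
  from mean promoter (TSS ± 3 kb) methylation plus promoter cluster
  features, evaluated over 100 random 80/20 splits with a permutation
  control.

A synthetic-data module generates cell-type-structured reads (with BAM
export via an XM-style call-string tag), in-silico mixtures and linked
expression labels, so the entire stack runs and is tested without any
external download. See the methods vignette
(`vignettes/epipattern-methods.Rmd`) for the full model description and
design rationale.

## Worked example

Simulate two small cell-type libraries, compare them, then impute one of
them and measure the coverage gain:

```r
library(epipattern)

cfg  <- simulationConfig(nBins = 300, depth = 20, seed = 7)
pr   <- simulateProfiles(cfg)
simA <- simulateReads(pr$profileA, cfg, seed = 1, label = "Bcell")
simB <- simulateReads(pr$profileB, cfg, seed = 2, label = "mono")

mats <- mapply(function(a, b)
  BinMatrix(binOf(a), rbind(callMatrix(a), callMatrix(b)),
            labels = c(readLabels(a), readLabels(b)),
            readIds = c(readIds(a), readIds(b))),
  simA$matrices, simB$matrices)

report <- clusterBins(mats, minReads = 10, minClusterSize = 4, seed = 3)
report
#> ClusterReport: 469 clusters in 234 bins (66 bins skipped), mode = two-library
head(as.data.frame(clusters(report)), 3)
#>   chrom bin_start bin_end pattern count_A count_B specificity class_A class_B
#> 1  chrS       100     200      11       7      12      shared   major   major
#> 2  chrS       100     200      01       6       1      shared   minor   minor
#> 3  chrS       200     300      11       5       7      shared   major   major
#>   bin_total_A bin_total_B
#> 1          13          13
#> 2          13          13
#> 3          10          10
summarizeUniqueFraction(report)
#>          A          B
#> 0.01918977 0.02771855
```

234 bins passed the coverage floor in both libraries; 469 clusters were
found (~2 per bin), and ~2–3 % of clusters are unique to one input —
these sit almost entirely in the ~8 % of simulated bins that carry a
cell type-specific epiallele.

```r
tr  <- prelimTrainingData(simA$matrices, seed = 4)
mod <- trainImputationModel(tr, grid = list(num_trees = c(50, 100),
                                            max_depth = c(5, 10)), seed = 5)
as.data.frame(mod@metrics)
#>   density n_train n_heldout       auc     auprc auc_baseline
#> 2       2     362        91 0.8919437 0.9658418    0.7710997
#> 3       3     355        89 0.8270308 0.9335841    0.7545518
#> 4       4     498       124 0.9658802 0.9877314    0.8232305
#> 5       5     124        31 0.9242424 0.9727088    0.9090909

imp <- imputeMatrices(mod, simA$matrices, confThreshold = 0.6)
unlist(coverageGain(simA$matrices, imp, minReads = 10))
#>     n_before      n_after percent_gain
#>    269.00000    297.00000     10.40892
```

Per CpG density, the forest's held-out AUC (0.83–0.97) exceeds the
column-mean baseline (0.75–0.91), and confidence-gated imputation lifts
the number of fully covered bins (≥ 10 complete reads) from 269 to 297
(+10 % at this simulated depth; gains grow as depth falls).

Real data enter through `binsFromReference()` (CpG positions from a
FASTA), `readBamCalls()` / `binMatrices()` (indexed Bismark-style BAM
with an XM tag), `compareLibraries()`, and `readBismarkCov()` /
`readBED()` for coverage tables, gene tables and DMR intervals. A thin
command-line front end (`exec/epipattern`) wraps the coverage, cluster
and simulate steps.

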