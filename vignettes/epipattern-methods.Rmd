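---
title: "Read-level methylation pattern analysis with epipattern"
author: "epipattern maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-level methylation pattern analysis with epipattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipattern)
```

# The model

Whole genome bisulfite sequencing (WGBS) reports, for every read, the
methylation state of each CpG the read covers. Because each read derives
from one DNA molecule in one cell, the ordered pattern of states along a
read — its *epiallele* — is a single-cell observation buried inside a bulk
library. `epipattern` analyses these patterns instead of the usual
per-site averages.

The procedure has two phases. Phase 1 tiles each chromosome into 100-bp
non-overlapping bins (0-based, half-open; a final partial bin is kept) and
counts, per bin, the *informative* reads: read segments covering every CpG
in the bin. Analysis is restricted to bins with at least two CpGs, since a
single site carries no pattern. Phase 2 extracts the reads of each
sufficiently covered bin into a reads × CpGs matrix over
{1 = methylated, 0 = unmethylated, −1 = not covered}, groups informative
reads by *exact pattern identity*, and keeps groups of at least
`minClusterSize` (default 4) reads as clusters. In a two-library
comparison, reads are pooled across libraries with their origin tracked;
a cluster with reads from only one library is *sample-specific*
(`A_only` / `B_only`), otherwise *shared*. Within each library, a cluster
holding at least 50% of that library's informative reads in the bin is
*major*, otherwise *minor*. Identity grouping is deterministic, so output
ordering is fixed (descending pooled count, ties by pattern) and results
are invariant to read order and to chromosome-parallel execution.

Two defaults matter. `minReads` (default 10 informative reads per library
per bin) sets the coverage floor below which a bin is skipped; and before
two-library clustering the deeper library is randomly down-sampled per bin
to the shallower library's informative depth (`equalizeDepth`, seeded).
Equalisation is on by default because an uncorrected 3:1 depth imbalance
would manufacture "sample-specific" clusters from sampling alone; it can
be disabled (`equalize = FALSE`) when the inputs are already matched. The
cluster-size threshold is implemented as a plain configurable count: we do
not attach a significance statement to the default of 4, because the
appropriate null depends on bin depth and pattern entropy, and the
threshold's role here is simply to separate recurrent epialleles from
singleton noise.

# Read-level imputation

Shotgun reads often cover only part of a bin, so many reads are
non-informative. The imputation engine recovers missing read-level CpG
states so those reads can participate in clustering.

Training data come from the library itself. Every observed matrix with at
least one missing cell donates its missingness *mask* (the set of missing
(row, column) cells), keyed by matrix shape. Complete matrices — the
informative rows of bins with ≥ 10 of them — are then artificially masked
with a randomly drawn same-shape mask, and each hidden cell becomes a
labelled example (one mask per complete matrix; more would reweight
densely covered bins). Each missing cell is encoded as a fixed-order
feature vector: the mean observed state on the read, the mean observed
state at the CpG position (the column mean), the raw row and column
indices, the number of observed CpGs on the read, the full row of states,
and the *read encodings* — the relative frequencies of each of the $2^d$
fully observed patterns among the bin's complete reads, indexed in
pattern-lexicographic order (first CpG most significant). The row-state
vector subsumes any separate "adjacent CpG" feature, so none is added.
The raw row/column indices have limited meaning across bins; they are
retained for completeness of the local encoding but carry little signal.

One probability forest is trained per CpG density $d \in \{2,3,4,5\}$
(densities outside this range pass through unimputed). Hyperparameters
are chosen by grid search — forest size {10, 50, 100, 500, 1000} × tree
depth {1, 5, 10, 20, 30} by default — scored by 5-fold cross-validated
AUC on an 80% partition, with AUC and AUPRC reported on the held-out 20%.
A missing cell receives the predicted methylation probability $y$ and the
confidence $C = |2(y - 0.5)|$; cells with $C$ strictly above the gate
(default 0.6) are called $1$ if $y > 0.5$, else $0$; an exact $y = 0.5$
has $C = 0$ and can never pass a positive gate, so no tie-break is
needed. Observed cells are never modified, and imputation can only grow
the set of fully covered bins. Models are trained genome-wide per
library; cross-library prediction works but is generally weaker than
predicting on the training library.

The natural baseline is the column mean — the average observed
methylation at the CpG position. On bins whose reads follow a small set
of recurrent patterns, the row context identifies which pattern a read
belongs to and the forest clearly outperforms this baseline; on bins
whose cells are independent Bernoulli draws per column, the column mean
is the optimal predictor and the forest can only match it. Both regimes
are exercised in the test suite.

# Downstream inference

**Mixture proportions.** Each in-silico mixture is clustered in
single-library mode (no second input is required), and the read count of
every (bin, pattern) cluster becomes one feature column; columns whose
bin overlaps a DMR interval (half-open BED overlap) are removed so the
features are orthogonal to conventional differential methylation.
Features are centred and projected onto the top 20 principal components
and a multivariate linear regression maps components to the mixture
proportion. Cross-validation refits the projection inside each fold so no
held-out information leaks. A test table is aligned to the training
columns first (train-only columns zero-filled, test-only columns
dropped); predictions are clipped to [0, 1], since a linear model can
stray slightly outside the unit interval.

**Expression prediction.** Differentially expressed genes are selected as
$\pm 2$ SD outliers of $\Delta \log_2(\mathrm{FPKM} + 1)$ (the
pseudocount of 1 keeps zero-FPKM genes finite and is recorded with the
output); the binary label is the sign. Per gene, features are the mean
methylation of promoter-window CpGs per cell type plus one read-count
column per (pattern, specificity) combination of clusters whose bin
intersects the window, optionally extended by decile-frequency vectors
(the fraction of promoter CpGs in [0,10), …, [90,100] percent
methylation). The promoter window is the half-open ±3-kb interval around
the TSS; being symmetric, it needs no strand arithmetic. A strand-aware
500-bp upstream-only window is available as an alternative. A bin
belongs to a promoter if its interval overlaps the window at all — bins
are 60× smaller than the window, so boundary effects are negligible, but
the rule is fixed for reproducibility. A probability forest is tuned
once by 10-fold cross-validated grid search and evaluated over 100
random 80/20 splits (held-out AUC per split); a nested mode re-optimises
the grid inside each outer fold, and a permutation mode shuffles labels
before everything else as the negative control. R forest
implementations split on Gini impurity, so the tuning grid covers forest
size and depth but not the impurity criterion.

# The synthetic generator

`simulationConfig()` fixes the study conditions the package is tested
under; the defaults are the conditions, not tuning knobs.

* **Bins and densities.** Bins carry 2–5 CpGs with probabilities
  0.4/0.3/0.2/0.1 — CpG-sparse bins dominate outside islands.
* **Epiallele distributions.** Shared bins follow a low-entropy
  categorical distribution: 0.55 on the fully methylated pattern
  (shared clusters tend to be fully methylated), 0.43 on one alternative
  epiallele, and 0.02 spread over rare patterns that model
  sub-threshold stochastic reads. Low entropy is deliberate: read-level
  analyses of real libraries find only ~1–2 clusters per bin on
  average, and a generator with many mid-frequency patterns would
  manufacture spurious "sample-specific" clusters from sampling noise
  alone, which real self-vs-self splits do not show.
* **Cell type-specific bins.** A configurable fraction (default 8%)
  plants a pattern with probability 0.6 in exactly one cell type and
  probability 0 in the other; the planted epiallele replaces the
  alternative pattern, representing the cell type's distinctive state.
* **Depth and missingness.** Per-bin read counts are Poisson around the
  configured depth (default 20), as in shotgun coverage. Missingness is
  read truncation — a random prefix or suffix of the bin's CpGs is
  hidden with probability 0.3 per read — mimicking reads that partially
  overlap a bin, the actual source of read-level missingness (random
  cell-dropout would misrepresent it and would also break the
  contiguity of real read segments).
* **Mixtures.** Each read is drawn from cell type A with probability
  $p$ and B otherwise at the same total depth, matching computational
  read mixing from pure libraries (proportions 10:90 … 90:10).
* **DMR-style bins.** Optionally, a fraction of bins differ in mean
  methylation between the cell types (mode mass 0.8 on all-methylated
  vs all-unmethylated); they are exported as intervals so feature
  exclusion can be exercised.
* **Expression data.** Genes get balanced binary labels; the label
  drives FPKM fold changes (so the label equals the sign of
  $\Delta\log_2$ FPKM by construction), a promoter methylation
  difference of ~6 percentage points against ~8 points of noise (the
  more expressed cell type is the less methylated — a weak,
  realistic signal), and an excess of label-concordant specific
  promoter clusters (Poisson counts, stronger for the ~30% of genes
  carrying a major cluster). Setting the effect size to 0 severs every
  feature–label link, providing the null.
* **BAM export.** Reads are written as SAM over a toy A/T reference
  with CG dinucleotides at the simulated positions, methylation encoded
  both in the sequence (C/T forward, G/A reverse) and in an XM-style
  call-string tag (on the G for reverse-strand reads, as bisulfite
  aligners report), then converted to a sorted, indexed BAM. Strand
  assignment is random per read, so the forward-strand collapsing of
  calls is exercised on every round trip.

What the generator does *not* emulate: bisulfite conversion failure,
sequencing errors and base qualities, PCR duplicates, mate-pair overlap,
CpG-density autocorrelation along the genome, and biological coupling
between neighbouring bins. Passing tests therefore demonstrate the
correctness and statistical behaviour of the machinery under the stated
generative assumptions, not performance on any particular real library.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; BAM's 1-based positions
  are converted at the boundary. Both-strand CpG calls collapse onto the
  forward-strand C so patterns are comparable across strands.
* Reads whose CIGAR is not a single match run (indels, clipping) are
  skipped and counted; call reconstruction through indels is out of
  scope. Paired-end mates are independent read segments; duplicate
  removal is assumed done upstream.
* A read with no observed state gets row mean 0.5 (an uninformative
  prior); an empty CpG column likewise predicts 0.5. A matrix with no
  complete rows gets an all-zero read-encoding block.
* Cluster output ordering, the per-bin equalisation seeds (derived
  deterministically from the run seed), and all generator draws are
  fixed by seeds; identical seeds give byte-identical training sets,
  chosen hyperparameters and imputed matrices.
* Proportion-model errors: fewer samples than components + 1 is an
  error instructing the user to lower `nComponents`; prediction on
  unaligned columns is an error pointing to `alignFeatures()`.

# Problem sizes used in the checks

The packaged checks run at desk scale: clustering oracles on 1000 random
matrices; self-vs-self versus cross-cell-type comparisons on 2000 bins at
depth 20 over 10 seeds; imputation benchmarking on 200–300 bins per seed
with a reduced tuning grid (forest size {50, 100} × depth {5, 10} — at
these training-set sizes the AUC comparison against the column-mean
baseline is insensitive to grid breadth); mixture recovery on 1000 bins ×
108 mixtures at depth 30 (the real analysis is genome-wide, and recovery
accuracy grows with the number of cell type-informative bins, so the bin
count is chosen large enough that the claim has adequate statistical
power at desk scale); expression prediction on 500 genes × 100 splits. These sizes were chosen so the full suite completes comfortably
on a laptop while every statistical conclusion remains stable across
seeds.

# Known limitations

* Exact-identity clustering treats a single discordant CpG as a
  different pattern; fuzzy grouping and linking clusters across adjacent
  bins into longer haplotypes are out of scope.
* Only CpG context is handled (no CHH/CHG), and densities above 5 CpGs
  per bin are never imputed.
* The two-library comparison supports exactly two inputs; multi-way
  deconvolution is not attempted.
* DMR calling itself is external: DMRs are consumed as BED intervals.
* The (pattern, specificity) promoter feature layout is one reasonable
  summary of cluster context; richer layouts (per-bin columns,
  major/minor split features) are possible and may behave differently.
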