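Package: epipattern
Title: Read-Level CpG Methylation Pattern Clustering, Imputation and
    Downstream Inference for WGBS Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies cell type-specific read-level CpG methylation
    patterns (epialleles) in whole genome bisulfite sequencing data.
    The genome is tiled into 100-bp bins, informative reads (reads
    covering every CpG in a bin) are grouped into clusters of identical
    methylation patterns, and clusters are labelled as shared or
    sample-specific and as major or minor within each library. A
    random-forest imputation engine recovers missing read-level CpG
    calls with a confidence gate, increasing the number of fully
    covered bins. Cluster read counts serve as features for two
    downstream inference procedures: estimation of cell-mixture
    proportions via principal components regression, and binary
    prediction of which of two cell types expresses a gene more highly
    from promoter methylation and promoter cluster features. A
    synthetic-data generator produces cell-type-structured reads,
    mixtures and linked expression labels so the whole stack can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    ranger,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
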