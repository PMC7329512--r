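# Shared fixtures and independent oracles used across test files.

# Merge the per-bin matrices of two simulated libraries into two-library
# matrices.
mergeLibraries <- function(matsA, matsB) {
  mapply(function(a, b)
    BinMatrix(binOf(a), rbind(callMatrix(a), callMatrix(b)),
              labels = c(readLabels(a), readLabels(b)),
              readIds = c(readIds(a), readIds(b))),
    matsA, matsB)
}

# Random BinMatrix over {-1,0,1} for property tests (uses the current RNG).
randomBinMatrix <- function(nReads, d, labels = "A", missingFrac = 0.2) {
  m <- matrix(sample(0:1, nReads * d, replace = TRUE), nReads, d)
  miss <- runif(nReads * d) < missingFrac
  m[miss] <- -1L
  bin <- BinSpec("chrT", 0L, 100L, seq(10L, by = 4L, length.out = d))
  labs <- sample(labels, nReads, replace = TRUE)
  BinMatrix(bin, m, labels = labs)
}

# Independent clustering oracle: a plain loop-and-dictionary tally of
# informative-read patterns with the minimum-size filter, sorted by
# descending pooled count then pattern.
bruteTally <- function(x, minClusterSize = 4L, libraries = NULL) {
  m <- callMatrix(x)
  labs <- readLabels(x)
  if (is.null(libraries)) libraries <- sort(unique(labs))
  counts <- list()
  for (r in seq_len(nrow(m))) {
    if (any(m[r, ] == -1L)) next
    pat <- paste(m[r, ], collapse = "")
    if (is.null(counts[[pat]]))
      counts[[pat]] <- setNames(rep(0L, length(libraries)), libraries)
    counts[[pat]][[labs[r]]] <- counts[[pat]][[labs[r]]] + 1L
  }
  keep <- names(counts)[vapply(counts, sum, numeric(1)) >= minClusterSize]
  if (length(keep) == 0L) {
    out <- data.frame(pattern = character(0), total = integer(0))
    for (l in libraries) out[[paste0("count_", l)]] <- integer(0)
    return(out)
  }
  out <- data.frame(pattern = keep,
                    total = vapply(counts[keep], function(z)
                      as.integer(sum(z)), integer(1)),
                    stringsAsFactors = FALSE)
  for (l in libraries)
    out[[paste0("count_", l)]] <-
      vapply(counts[keep], function(z) as.integer(z[[l]]), integer(1))
  out <- out[order(-out$total, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Build a two-library ClusterReport directly from a cluster table
# (used by tests that exercise report summaries without a full run).
makeReport <- function(df, mode = "two-library") {
  methods::new("ClusterReport", clusters = S4Vectors::DataFrame(df),
               params = list(mode = mode, libraries = c("A", "B"),
                             min_reads = 10L, min_cluster_size = 4L,
                             seed = NULL, equalize = TRUE),
               nBinsProcessed = length(unique(df$bin_start)),
               nBinsSkipped = 0L)
}

# Small hyperparameter grid keeping forest training fast in tests.
smallGrid <- list(num_trees = c(50, 100), max_depth = c(5, 10))
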