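#' Construct a BinSpec
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bin coordinates (end - start <= 100).
#' @param cpgPositions Integer vector of 0-based CpG C positions within
#'   the bin, strictly increasing.
#' @return A [BinSpec-class] object.
#' @examples
#' b <- BinSpec("chr1", 1000L, 1100L, c(1010L, 1050L))
#' binDensity(b)
#' @export
BinSpec <- function(chrom, start, end, cpgPositions = integer(0)) {
  new("BinSpec", chrom = as.character(chrom), start = as.integer(start),
      end = as.integer(end), cpgPositions = as.integer(cpgPositions))
}

#' Construct a BinMatrix
#'
#' @param bin A [BinSpec-class].
#' @param calls Matrix over \{-1, 0, 1\}, one column per bin CpG.
#' @param labels Per-row library labels (recycled if scalar).
#' @param readIds Per-row read identifiers; defaults to \code{read1..n}.
#' @return A [BinMatrix-class] object.
#' @export
BinMatrix <- function(bin, calls, labels = "A", readIds = NULL) {
  calls <- matrix(as.integer(calls), nrow = NROW(calls), ncol = NCOL(calls))
  if (length(labels) == 1L) labels <- rep(labels, nrow(calls))
  if (is.null(readIds)) readIds <- sprintf("read%d", seq_len(nrow(calls)))
  new("BinMatrix", bin = bin, calls = calls,
      labels = as.character(labels), readIds = as.character(readIds))
}

#' Tile chromosomes into non-overlapping 100-bp bins
#'
#' Bins tile each chromosome from position 0 in 0-based half-open
#' coordinates; all bins have size \code{binSize} except a possible final
#' partial bin retained at the chromosome end.
#'
#' @param chromLengths Named integer vector of chromosome lengths (bp).
#' @param binSize Bin width in bp (default 100).
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @examples
#' enumerateBins(c(chr1 = 250))
#' @export
enumerateBins <- function(chromLengths, binSize = 100L) {
  stopifnot(all(chromLengths >= 0), binSize >= 1)
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  out <- lapply(names(chromLengths), function(ch) {
    len <- as.integer(chromLengths[[ch]])
    if (len == 0L) return(NULL)
    starts <- seq.int(0L, len - 1L, by = binSize)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + as.integer(binSize), len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  out
}

#' Build BinSpec objects by scanning a reference for CpG sites
#'
#' Tiles each reference sequence into bins and locates CpG dinucleotides
#' (forward-strand "CG" matches; the C position is recorded, 0-based).
#'
#' @param reference A [Biostrings::DNAStringSet-class] or path to a FASTA
#'   file.
#' @param binSize Bin width in bp.
#' @param minCpGs Drop bins with fewer CpGs than this (default 0, keep all).
#' @return A list of [BinSpec-class] objects.
#' @export
binsFromReference <- function(reference, binSize = 100L, minCpGs = 0L) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  bins <- list()
  for (ch in names(reference)) {
    seq <- reference[[ch]]
    hits <- Biostrings::matchPattern("CG", seq)
    cpg0 <- BiocGenerics::start(hits) - 1L   # 0-based C position
    tiles <- enumerateBins(stats::setNames(length(seq), ch), binSize)
    idx <- findInterval(cpg0, tiles$start)
    for (i in seq_len(nrow(tiles))) {
      p <- cpg0[idx == i]
      if (length(p) < minCpGs) next
      bins[[length(bins) + 1L]] <-
        BinSpec(ch, tiles$start[i], tiles$end[i], p)
    }
  }
  bins
}

#' Export a set of bins as a BED file
#'
#' Writes 0-based half-open intervals (chrom, start, end), suitable for
#' external enrichment tools.
#'
#' @param bins A data.frame with \code{chrom}, \code{start}, \code{end}
#'   columns, or a list of [BinSpec-class] objects.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
exportBED <- function(bins, file) {
  if (is.list(bins) && !is.data.frame(bins))
    bins <- data.frame(
      chrom = vapply(bins, binChrom, character(1)),
      start = vapply(bins, binStart, integer(1)),
      end = vapply(bins, binEnd, integer(1)))
  utils::write.table(bins[, c("chrom", "start", "end")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
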