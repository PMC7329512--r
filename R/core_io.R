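#' Parse a Bismark-style methylation call string into per-CpG calls
#'
#' Bisulfite-aware aligners record, for every read, a call string of the
#' same length as the aligned sequence in which CpG-context cytosines
#' appear as \code{Z} (methylated) or \code{z} (unmethylated); all other
#' characters are ignored here. For a read aligned without indels, the
#' character at offset \eqn{i} (0-based) corresponds to reference position
#' \code{pos + i}. For reverse-strand reads the CpG call sits on the G of
#' the dinucleotide in forward-strand coordinates; calls are shifted by -1
#' so that both strands report the forward-strand C position.
#'
#' @param callString The per-read methylation call string (e.g. from the
#'   XM auxiliary tag).
#' @param pos 0-based reference position of the first aligned base.
#' @param reverse Logical; \code{TRUE} for a reverse-strand alignment.
#' @return Named integer vector of calls (1 = methylated, 0 =
#'   unmethylated); names are 0-based forward-strand C positions. Empty if
#'   the string carries no CpG-context calls.
#' @examples
#' parseMethylationCalls("..Z....z..", 1000)
#' @export
parseMethylationCalls <- function(callString, pos, reverse = FALSE) {
  stopifnot(length(callString) == 1L, !is.na(callString))
  off <- gregexpr("[Zz]", callString)[[1]]
  if (off[1] == -1L) return(stats::setNames(integer(0), character(0)))
  chars <- substring(callString, off, off)
  p <- as.integer(pos) + as.integer(off) - 1L - as.integer(reverse)
  stats::setNames(as.integer(chars == "Z"), p)
}

## Vectorised call-string parser used by the BAM reader. Returns one row
## per CpG-context call: readId, chrom, pos (0-based forward-strand C),
## state.
.parseCallsMany <- function(readId, chrom, pos0, reverse, xm) {
  hits <- gregexpr("[Zz]", xm)
  nper <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h),
                 integer(1))
  keep <- nper > 0L
  if (!any(keep))
    return(data.frame(readId = character(0), chrom = character(0),
                      pos = integer(0), state = integer(0)))
  idx <- rep(which(keep), nper[keep])
  off <- unlist(hits[keep])
  chars <- substring(xm[idx], off, off)
  data.frame(
    readId = readId[idx],
    chrom = chrom[idx],
    pos = pos0[idx] + off - 1L - as.integer(reverse[idx]),
    state = as.integer(chars == "Z"),
    stringsAsFactors = FALSE)
}

#' Read all per-read CpG calls from a bisulfite BAM file
#'
#' Scans a coordinate-sorted BAM file and extracts every read's CpG-context
#' methylation calls from its call-string tag. Reads whose CIGAR contains
#' anything other than a single match run (i.e. indels or clipping) are
#' skipped and counted; call reconstruction through indels is not
#' attempted.
#'
#' @param bamFile Path to an indexed BAM file.
#' @param label Library label attached to every read (defaults to the file
#'   name without extension).
#' @param tag Name of the auxiliary tag holding the call string (default
#'   \code{"XM"}).
#' @param which Optional [GenomicRanges::GRanges-class] restricting the
#'   scan (1-based, as returned by \code{binAsGRanges}).
#' @return A list with elements \code{calls} (data.frame: \code{readId},
#'   \code{chrom}, \code{pos}, \code{state}, \code{label}) and
#'   \code{nSkippedIndel}.
#' @export
readBamCalls <- function(bamFile, label = NULL, tag = "XM", which = NULL) {
  if (is.null(label))
    label <- sub("\\.bam$", "", basename(bamFile))
  what <- c("qname", "flag", "rname", "pos", "cigar")
  param <- if (is.null(which))
    Rsamtools::ScanBamParam(what = what, tag = tag)
  else
    Rsamtools::ScanBamParam(what = what, tag = tag, which = which)
  res <- tryCatch(Rsamtools::scanBam(bamFile, param = param),
                  error = function(e)
                    stop("cannot read alignment file '", bamFile, "': ",
                         conditionMessage(e)))
  res <- do.call(Map, c(list(f = c), res))  # merge ranges if 'which' given
  xm <- res[["tag"]]
  if (is.list(xm)) xm <- unlist(xm, use.names = FALSE)
  qname <- res$qname
  n <- length(qname)
  if (n == 0L)
    return(list(calls = data.frame(readId = character(0),
                                   chrom = character(0), pos = integer(0),
                                   state = integer(0), label = character(0)),
                nSkippedIndel = 0L))
  if (is.null(xm) || length(xm) != n || anyNA(xm)) {
    bad <- if (!is.null(xm) && length(xm) == n) qname[which(is.na(xm))[1]]
           else qname[1]
    stop("read '", bad, "' in '", bamFile, "' lacks the ", tag, " tag")
  }
  pureM <- grepl("^[0-9]+M$", res$cigar)
  nskip <- sum(!pureM)
  if (nskip > 0L)
    message(nskip, " read(s) with indels/clipping skipped in ",
            basename(bamFile))
  keep <- pureM
  calls <- .parseCallsMany(
    readId = qname[keep],
    chrom = as.character(res$rname)[keep],
    pos0 = res$pos[keep] - 1L,
    reverse = bitwAnd(res$flag[keep], 16L) > 0L,
    xm = xm[keep])
  calls$label <- rep(label, nrow(calls))
  list(calls = calls, nSkippedIndel = nskip)
}

#' Convert a BinSpec to a 1-based GRanges interval
#'
#' @param bin A [BinSpec-class].
#' @return A length-1 [GenomicRanges::GRanges-class].
#' @export
binAsGRanges <- function(bin) {
  GenomicRanges::GRanges(binChrom(bin),
                         IRanges::IRanges(binStart(bin) + 1L, binEnd(bin)))
}

#' Assemble per-bin read-call matrices from parsed calls
#'
#' Distributes per-read CpG calls into the supplied bins and builds one
#' [BinMatrix-class] per bin: rows are read segments overlapping at least
#' one bin CpG, columns the bin's CpGs, entries -1 where the read does not
#' cover the CpG. Row order is deterministic (read id, then library).
#'
#' @param calls A data.frame as produced by [readBamCalls()] (or the
#'   concatenation of several libraries' calls), with columns
#'   \code{readId}, \code{chrom}, \code{pos}, \code{state}, \code{label}.
#' @param bins List of [BinSpec-class] objects with disjoint CpG sets.
#' @return A list of [BinMatrix-class], one per bin (possibly with zero
#'   rows).
#' @export
binMatrices <- function(calls, bins) {
  d <- vapply(bins, binDensity, integer(1))
  posKey <- unlist(lapply(seq_along(bins), function(i)
    paste0(binChrom(bins[[i]]), ":", cpgPositions(bins[[i]]))))
  binIdx <- rep(seq_along(bins), d)
  colIdx <- unlist(lapply(d, seq_len))
  j <- match(paste0(calls$chrom, ":", calls$pos), posKey)
  keep <- which(!is.na(j))
  cb <- binIdx[j[keep]]
  cc <- colIdx[j[keep]]
  rid <- calls$readId[keep]
  lab <- calls$label[keep]
  st <- calls$state[keep]
  out <- vector("list", length(bins))
  byBin <- split(seq_along(cb), factor(cb, levels = seq_along(bins)))
  for (i in seq_along(bins)) {
    sel <- byBin[[i]]
    if (length(sel) == 0L) {
      out[[i]] <- BinMatrix(bins[[i]],
                            matrix(integer(0), 0L, d[i]),
                            labels = character(0), readIds = character(0))
      next
    }
    key <- paste0(rid[sel], "\r", lab[sel])
    ukey <- sort(unique(key))
    r <- match(key, ukey)
    m <- matrix(-1L, length(ukey), d[i])
    m[cbind(r, cc[sel])] <- st[sel]
    parts <- strsplit(ukey, "\r", fixed = TRUE)
    out[[i]] <- BinMatrix(bins[[i]], m,
                          labels = vapply(parts, `[`, character(1), 2L),
                          readIds = vapply(parts, `[`, character(1), 1L))
  }
  out
}

#' Load the read-call matrix of a single bin from BAM files
#'
#' Extracts reads overlapping the bin from one or two indexed BAM files
#' and assembles the reads x CpGs matrix with per-row library labels.
#'
#' @param bamFiles Character vector of one or two indexed BAM paths.
#' @param bin A [BinSpec-class] with density >= 1.
#' @param labels Library labels, one per file (default file basenames).
#' @param tag Call-string tag name.
#' @return A [BinMatrix-class]; zero rows if no reads overlap.
#' @export
loadBinMatrix <- function(bamFiles, bin, labels = NULL, tag = "XM") {
  stopifnot(binDensity(bin) >= 1L)
  if (is.null(labels))
    labels <- sub("\\.bam$", "", basename(bamFiles))
  gr <- binAsGRanges(bin)
  allCalls <- do.call(rbind, lapply(seq_along(bamFiles), function(i)
    readBamCalls(bamFiles[i], label = labels[i], tag = tag,
                 which = gr)$calls))
  binMatrices(allCalls, list(bin))[[1]]
}

#' Write a per-bin coverage table
#'
#' @param coverage A data.frame as returned by [coverageTable()].
#' @param file Output TSV path.
#' @return Invisibly, the path.
#' @export
writeCoverageTable <- function(coverage, file) {
  out <- coverage[, c("chrom", "bin_start", "bin_end", "n_cpgs",
                      "n_informative_reads")]
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a Bismark-style CpG coverage table
#'
#' Expected columns: chromosome, start, end (1-based, start == end for a
#' single CpG), methylation percentage, methylated count, unmethylated
#' count.
#'
#' @param file Path to an (uncompressed) coverage file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{meth_pct}, \code{count_m}, \code{count_u}.
#' @export
readBismarkCov <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L)
    stop("coverage file '", file, "' must have 6 columns")
  names(df)[1:6] <- c("chrom", "start", "end", "meth_pct", "count_m",
                      "count_u")
  df[, 1:6]
}

#' Write a Bismark-style CpG coverage table
#'
#' @param df data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{meth_pct}, \code{count_m}, \code{count_u}.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
writeBismarkCov <- function(df, file) {
  utils::write.table(df[, c("chrom", "start", "end", "meth_pct",
                            "count_m", "count_u")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
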