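#' Read aligned reads from a SAM/BAM file
#'
#' Loads primary alignments with the fields the accuracy and coverage
#' computations need: query length, CIGAR insertion/deletion totals, the
#' NM edit-distance tag, and a per-read mean quality. Secondary and
#' supplementary alignments are dropped. The per-read quality is the
#' ONT-style aggregate: mean per-base error probability converted back to
#' the Phred scale, \eqn{-10 \log_{10}(\overline{10^{-Q/10}})}.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @return A data.frame with one row per primary alignment: \code{qname},
#'   \code{pos}, \code{queryLength}, \code{refSpan}, \code{cigar},
#'   \code{nm} (NA when the tag is absent), \code{insertionLength},
#'   \code{deletionLength}, \code{meanQuality}, \code{mapped}.
#' @export
readSamReads <- function(path) {
  isBam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (isBam) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar", "qual", "qwidth"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]

  primary <- bitwAnd(x$flag, 256L) == 0L & bitwAnd(x$flag, 2048L) == 0L
  mapped <- bitwAnd(x$flag, 4L) == 0L
  keep <- primary
  cig <- x$cigar[keep]
  cig[is.na(cig)] <- ""
  opTab <- GenomicAlignments::cigarOpTable(cig)

  refSpan <- rep(0L, length(cig))
  nonEmpty <- nzchar(cig)
  refSpan[nonEmpty] <-
    GenomicAlignments::cigarWidthAlongReferenceSpace(cig[nonEmpty])

  qual <- methods::as(x$qual[keep], "IntegerList")
  meanQ <- vapply(qual, function(q) {
    if (!length(q)) return(NA_real_)
    -10 * log10(mean(10^(-q / 10)))
  }, numeric(1))

  data.frame(
    qname = x$qname[keep],
    pos = x$pos[keep],
    queryLength = x$qwidth[keep],
    refSpan = refSpan,
    cigar = x$cigar[keep],
    nm = as.integer(x$tag$NM[keep]),
    insertionLength = as.integer(opTab[, "I"]),
    deletionLength = as.integer(opTab[, "D"]),
    meanQuality = meanQ,
    mapped = mapped[keep],
    stringsAsFactors = FALSE)
}

#' Filter reads on length and quality
#'
#' Applies the read-level QC rule used for low-pass nanopore data: reads
#' with length <= \code{minLength} bp or mean quality score below
#' \code{minQuality} are discarded. Reads with a missing quality are
#' treated as failing and counted separately.
#'
#' @param reads data.frame with columns \code{queryLength} and
#'   \code{meanQuality} (e.g. from \code{\link{readSamReads}}).
#' @param minLength length threshold in bp; retained reads are strictly
#'   longer.
#' @param minQuality quality threshold; retained reads have quality
#'   \code{>= minQuality}.
#' @return A list with \code{reads} (the retained subset) and
#'   \code{counts}: named integers \code{retained}, \code{tooShort},
#'   \code{lowQuality}, \code{missingQuality} (a read failing both rules
#'   counts as too short).
#' @examples
#' rd <- data.frame(queryLength = c(150, 151, 10000),
#'                  meanQuality = c(20, 10, 9.99))
#' filterReads(rd)$counts
#' @export
filterReads <- function(reads, minLength = 150, minQuality = 10) {
  stopifnot(all(c("queryLength", "meanQuality") %in% names(reads)))
  missingQ <- is.na(reads$meanQuality)
  tooShort <- reads$queryLength <= minLength
  lowQ <- !missingQ & !tooShort & reads$meanQuality < minQuality
  keep <- !tooShort & !missingQ & reads$meanQuality >= minQuality
  list(
    reads = reads[keep, , drop = FALSE],
    counts = c(retained = sum(keep),
               tooShort = sum(tooShort),
               lowQuality = sum(lowQ),
               missingQuality = sum(missingQ & !tooShort)))
}

#' Total mismatch score (TMS) of a read
#'
#' The single-nucleotide mismatch count of a read: the NM edit distance
#' minus the total inserted and deleted bases taken from the CIGAR. The
#' result is clamped at zero because NM conventions differ slightly
#' between aligners; a negative raw value indicates tag dialect, not
#' negative error.
#'
#' @param nm NM tag value(s); NA propagates.
#' @param insertionLength total CIGAR I length per read.
#' @param deletionLength total CIGAR D length per read.
#' @return Integer vector of TMS values (>= 0).
#' @examples
#' computeTms(10, 3, 2)  # 5
#' @export
computeTms <- function(nm, insertionLength = 0L, deletionLength = 0L) {
  pmax(as.integer(nm) - as.integer(insertionLength) -
         as.integer(deletionLength), 0L)
}

#' Per-read basecalling accuracy
#'
#' Accuracy = 1 - TMS / read length, the fraction of query bases that are
#' not single-nucleotide mismatches against the reference. Read length is
#' the full query sequence length (soft-clipped bases included) by
#' default; pass aligned lengths instead to use the aligned-span
#' convention.
#'
#' @param tms total mismatch score per read (>= 0).
#' @param readLength read length in bp (>= 1).
#' @return Numeric accuracy in [0, 1].
#' @examples
#' readAccuracy(5, 1000)  # 0.995
#' @export
readAccuracy <- function(tms, readLength) {
  if (any(readLength < 1)) stop("readLength must be >= 1")
  if (any(tms < 0)) stop("tms must be >= 0")
  if (any(tms > readLength, na.rm = TRUE))
    stop("tms exceeds read length: inconsistent alignment")
  1 - tms / readLength
}

#' Summarize a set of per-read accuracies
#'
#' Median is the standard sample median. Mode is estimated from a
#' fixed-width histogram on the accuracy scale: the midpoint of the
#' highest-count bin, ties broken toward the higher-accuracy bin.
#'
#' @param accuracies numeric vector in [0, 1], at least one value.
#' @param binWidth histogram bin width on the accuracy scale.
#' @return A list: \code{median}, \code{mode}, \code{n}, and
#'   \code{histogram} (data.frame of bin \code{lower}, \code{upper},
#'   \code{count}).
#' @export
summarizeAccuracy <- function(accuracies, binWidth = 0.001) {
  if (!length(accuracies)) stop("at least one accuracy value is required")
  if (any(accuracies < 0 | accuracies > 1))
    stop("accuracies must lie in [0, 1]")
  breaks <- seq(0, 1, by = binWidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  # left-closed bins; accuracy exactly 1 falls in the last bin
  idx <- pmin(findInterval(accuracies, breaks), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  best <- max(which(counts == max(counts)))        # tie -> higher accuracy
  list(
    median = median(accuracies),
    mode = (breaks[best] + breaks[best + 1L]) / 2,
    n = length(accuracies),
    histogram = data.frame(lower = breaks[-length(breaks)],
                           upper = breaks[-1L], count = counts))
}

#' Depth and breadth of coverage
#'
#' Mean depth is total aligned reference bases divided by the reference
#' length; breadth is the percentage of reference positions covered by at
#' least one aligned base.
#'
#' @param start,refSpan alignment start (1-based) and reference span per
#'   read, e.g. from \code{\link{readSamReads}}.
#' @param referenceLength reference length in bp (> 0).
#' @return A list: \code{meanDepth} (fold) and \code{breadth} (percent).
#' @examples
#' coverageStats(start = 1, refSpan = 100, referenceLength = 1000)
#' @export
coverageStats <- function(start, refSpan, referenceLength) {
  if (referenceLength <= 0) stop("referenceLength must be > 0")
  ir <- IRanges::IRanges(start = start, width = refSpan)
  cov <- IRanges::coverage(ir, width = as.integer(referenceLength))
  totalBases <- sum(as.numeric(S4Vectors::runLength(cov)) *
                      as.numeric(S4Vectors::runValue(cov)))
  covered <- sum(as.numeric(S4Vectors::runLength(cov))[
    S4Vectors::runValue(cov) >= 1L])
  list(meanDepth = totalBases / referenceLength,
       breadth = 100 * covered / referenceLength)
}
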