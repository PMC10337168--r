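#' Simulate per-CpG 5mC methylation calls
#'
#' Draws CpG site positions uniformly along a chromosome, a true
#' methylation level per site from a two-component Beta mixture
#' (hypomethylated and hypermethylated sites, the bimodal pattern typical
#' of vertebrate genomes), Poisson read coverage at \code{meanCoverage},
#' and a Binomial(coverage, level) modified-read count. Sites with zero
#' coverage are omitted from the emitted records, as a bedMethyl file
#' would omit them, but kept in the returned truth table.
#'
#' @param nSites number of CpG sites.
#' @param meanCoverage Poisson mean coverage lambda.
#' @param genomeLength chromosome length in bp.
#' @param hyperWeight mixture weight of the hypermethylated component.
#' @param hypoShape,hyperShape length-2 Beta shape parameters of the two
#'   components.
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return A list: \code{sites}, a \code{GRanges} of covered sites with
#'   metadata \code{coverage}, \code{percentModified} and
#'   \code{trueLevel}; and \code{truth}, a data.frame over all sites
#'   (position, trueLevel, coverage, modified).
#' @export
simulateMethylation <- function(nSites, meanCoverage = 2,
                                genomeLength = 1e7L, hyperWeight = 0.7,
                                hypoShape = c(1.5, 8),
                                hyperShape = c(8, 1.5),
                                chrom = "1", seed = 1L) {
  stopifnot(nSites >= 1, meanCoverage > 0,
            hyperWeight >= 0, hyperWeight <= 1)
  set.seed(stageSeed(seed, "methylation"))
  pos <- sort(sample.int(as.integer(genomeLength), nSites))
  hyper <- runif(nSites) < hyperWeight
  level <- ifelse(hyper,
                  rbeta(nSites, hyperShape[1], hyperShape[2]),
                  rbeta(nSites, hypoShape[1], hypoShape[2]))
  cov <- rpois(nSites, meanCoverage)
  modified <- rbinom(nSites, cov, level)
  keep <- cov >= 1L
  sites <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos[keep], width = 1L),
    strand = "+",
    coverage = cov[keep],
    percentModified = 100 * modified[keep] / cov[keep],
    trueLevel = level[keep])
  list(sites = sites,
       truth = data.frame(pos = pos, trueLevel = level, coverage = cov,
                          modified = modified))
}

#' Write 5mC sites to a bedMethyl (BED9+2) file
#'
#' Columns: chrom, start (0-based), end, name, score (coverage capped at
#' 1000), strand, thickStart, thickEnd, rgb, coverage, percent modified.
#'
#' @param sites \code{GRanges} with \code{coverage} and
#'   \code{percentModified} metadata.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBedMethyl <- function(sites, path) {
  start0 <- GenomicRanges::start(sites) - 1L
  end <- GenomicRanges::end(sites)
  strand <- as.character(GenomicRanges::strand(sites))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t5mC\t%d\t%s\t%d\t%d\t0,0,0\t%d\t%.2f",
                   as.character(GenomicRanges::seqnames(sites)),
                   start0, end,
                   pmin(sites$coverage, 1000L), strand, start0, end,
                   sites$coverage, sites$percentModified)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedMethyl (BED9+2) file into a GRanges
#'
#' BED coordinates are 0-based half-open; the returned \code{GRanges}
#' uses 1-based closed coordinates.
#'
#' @param path bedMethyl file.
#' @return \code{GRanges} with metadata \code{coverage} and
#'   \code{percentModified}.
#' @export
readBedMethyl <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = list(V1 = "character"))
  if (ncol(d) < 11)
    stop("bedMethyl requires 11 columns (BED9 + coverage + percent)")
  GenomicRanges::GRanges(
    seqnames = d$V1,
    ranges = IRanges::IRanges(start = d$V2 + 1L, end = d$V3),
    strand = ifelse(d$V6 %in% c("+", "-"), d$V6, "*"),
    coverage = as.integer(d$V10),
    percentModified = as.numeric(d$V11))
}

#' Coverage filter for methylation sites
#'
#' Retains sites with read coverage at or above the threshold. Thresholds
#' of 4, 7 and 10 reads are the usual ladder for low-pass 5mC data; the
#' site sets are nested, so a stricter filter always keeps a subset.
#'
#' @param sites \code{GRanges} with a \code{coverage} column.
#' @param minCoverage positive integer threshold (inclusive).
#' @return The filtered \code{GRanges}.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(1:3, width = 1),
#'                              coverage = c(3, 4, 10),
#'                              percentModified = c(0, 50, 100))
#' length(coverageFilter(gr, 4))
#' @export
coverageFilter <- function(sites, minCoverage = 4L) {
  if (minCoverage < 1) stop("minCoverage must be a positive integer")
  sites[sites$coverage >= minCoverage]
}

#' Bin methylation into fixed-width genomic windows
#'
#' Aggregates per-site percent methylation into genomic bins of
#' \code{binWidth} bp (default 500), weighting each site by its read
#' coverage. Empty bins are omitted.
#'
#' @param sites \code{GRanges} with \code{coverage} and
#'   \code{percentModified}.
#' @param binWidth bin width in bp (> 0).
#' @return data.frame with \code{chrom}, \code{binStart} (0-based),
#'   \code{meanPercent} (coverage-weighted), \code{nSites},
#'   \code{totalCoverage}.
#' @export
binMethylation <- function(sites, binWidth = 500L) {
  if (binWidth <= 0) stop("binWidth must be positive")
  if (!length(sites))
    return(data.frame(chrom = character(), binStart = integer(),
                      meanPercent = numeric(), nSites = integer(),
                      totalCoverage = integer()))
  start0 <- GenomicRanges::start(sites) - 1L
  key <- paste(as.character(GenomicRanges::seqnames(sites)),
               (start0 %/% binWidth) * binWidth, sep = ":")
  w <- as.numeric(sites$coverage)
  num <- tapply(w * sites$percentModified, key, sum)
  den <- tapply(w, key, sum)
  nS <- tapply(w, key, length)
  parts <- strsplit(names(num), ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    binStart = as.integer(vapply(parts, `[`, character(1), 2L)),
    meanPercent = as.numeric(num / den),
    nSites = as.integer(nS),
    totalCoverage = as.integer(den),
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$binStart), , drop = FALSE]
}

#' Agreement between two binned methylation profiles
#'
#' Pearson correlation of bin mean methylation over the bins present in
#' both profiles — the usual check that a stricter coverage filter leaves
#' the regional methylation landscape unchanged.
#'
#' @param profileA,profileB outputs of \code{\link{binMethylation}}.
#' @return A list: \code{correlation} and \code{nShared}. Fewer than 3
#'   shared bins leaves the correlation \code{NA} with a warning.
#' @export
filterAgreement <- function(profileA, profileB) {
  keyA <- paste(profileA$chrom, profileA$binStart)
  keyB <- paste(profileB$chrom, profileB$binStart)
  shared <- intersect(keyA, keyB)
  if (length(shared) < 3) {
    warning("fewer than 3 shared bins: correlation undefined")
    return(list(correlation = NA_real_, nShared = length(shared)))
  }
  a <- profileA$meanPercent[match(shared, keyA)]
  b <- profileB$meanPercent[match(shared, keyB)]
  list(correlation = cor(a, b), nShared = length(shared))
}
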