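#' Build a reference-panel index keyed by site and alternate allele
#'
#' @param chrom,pos,alt vectors describing the panel variants; matching in
#'   the depth-rescue filter requires the alternate allele to agree, not
#'   just the position.
#' @return A character vector of unique "chrom:pos:alt" keys with class
#'   \code{"PanelIndex"}.
#' @export
panelIndex <- function(chrom, pos, alt) {
  keys <- unique(paste(chrom, pos, alt, sep = ":"))
  structure(keys, class = "PanelIndex")
}

#' Depth-rescue filter for low-pass variant calls
#'
#' Variants with sequencing depth at or below \code{maxDiscardDepth} are
#' discarded unless the variant (site and alternate allele) is present in
#' the reference panel, in which case the panel rescues it. Calls with a
#' missing depth are discarded and counted separately.
#'
#' @param calls data.frame with columns \code{chrom}, \code{pos},
#'   \code{alt} and \code{depth}.
#' @param panel a \code{\link{panelIndex}} (or character keys).
#' @param maxDiscardDepth depth at or below which a call needs panel
#'   support to survive.
#' @return A list: \code{calls} (retained rows) and \code{counts} with
#'   \code{keptDepth} (depth above threshold), \code{rescued} (low depth,
#'   in panel), \code{discardedLowDepth}, \code{discardedMissingDepth}.
#' @examples
#' pnl <- panelIndex("1", c(100, 200), c("A", "T"))
#' calls <- data.frame(chrom = "1", pos = c(100, 300, 400),
#'                     alt = c("A", "C", "G"), depth = c(2, 2, 3))
#' depthRescueFilter(calls, pnl)$counts
#' @export
depthRescueFilter <- function(calls, panel, maxDiscardDepth = 2) {
  stopifnot(all(c("chrom", "pos", "alt", "depth") %in% names(calls)))
  keys <- paste(calls$chrom, calls$pos, calls$alt, sep = ":")
  missingDepth <- is.na(calls$depth)
  deep <- !missingDepth & calls$depth > maxDiscardDepth
  inPanel <- keys %in% unclass(panel)
  rescued <- !missingDepth & !deep & inPanel
  keep <- deep | rescued
  list(
    calls = calls[keep, , drop = FALSE],
    counts = c(keptDepth = sum(deep),
               rescued = sum(rescued),
               discardedLowDepth = sum(!missingDepth & !keep),
               discardedMissingDepth = sum(missingDepth)))
}

#' Assign zygosity from the within-sample alternate-allele fraction
#'
#' A heterozygous position is called when the alt-read fraction at the
#' site is larger than 0 and lower than \code{hetMax} (default 90%);
#' a fraction of exactly 0 is homozygous reference and a fraction at or
#' above \code{hetMax} is homozygous alternate. The fraction is the
#' within-sample allele fraction, not a population frequency.
#'
#' @param altFraction numeric in [0, 1].
#' @param hetMax exclusive upper bound of the heterozygous band.
#' @return Factor with levels \code{hom_ref}, \code{het}, \code{hom_alt}.
#' @examples
#' callZygosity(c(0, 0.5, 0.90))
#' @export
callZygosity <- function(altFraction, hetMax = 0.90) {
  if (any(is.na(altFraction)) ||
      any(altFraction < 0 | altFraction > 1))
    stop("altFraction must lie in [0, 1]")
  cls <- ifelse(altFraction == 0, "hom_ref",
                ifelse(altFraction < hetMax, "het", "hom_alt"))
  factor(cls, levels = c("hom_ref", "het", "hom_alt"))
}

#' Split multi-allelic call records into per-alt records
#'
#' Records whose ALT holds several comma-separated alleles are expanded
#' into one record per alternate allele; a comma-separated alt fraction is
#' distributed accordingly, otherwise the fraction is carried to each.
#'
#' @param calls data.frame with at least \code{alt}; optionally
#'   \code{altFraction} with matching comma-separated values.
#' @return The expanded data.frame.
#' @export
splitMultiallelic <- function(calls) {
  alts <- strsplit(as.character(calls$alt), ",", fixed = TRUE)
  n <- lengths(alts)
  out <- calls[rep(seq_len(nrow(calls)), n), , drop = FALSE]
  out$alt <- unlist(alts)
  if ("altFraction" %in% names(calls) && is.character(calls$altFraction)) {
    afs <- strsplit(calls$altFraction, ",", fixed = TRUE)
    bad <- lengths(afs) != n
    afs[bad] <- lapply(which(bad), function(i) rep(afs[[i]][1L], n[i]))
    out$altFraction <- as.numeric(unlist(afs))
  }
  rownames(out) <- NULL
  out
}

#' Read site-level variant calls from a VCF file
#'
#' Extracts the fields the filtering rules need — chromosome, position,
#' ref/alt alleles, depth (FORMAT/INFO DP) and alt-allele fraction
#' (FORMAT/INFO AF or VAF) — and splits multi-allelic records into
#' per-alt rows. Records with a missing DP are kept but flagged via
#' \code{NA} depth so the depth filter can count them.
#'
#' @param path a VCF v4.x file (plain or bgzipped).
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{depth}, \code{altFraction}, \code{genotype} (GT
#'   string or NA).
#' @export
readVcfCalls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))                     # single-record file
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  getInfo <- function(key) {
    val <- suppressWarnings(vcfR::extract.info(v, element = key,
                                               as.numeric = FALSE))
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  getFmt <- function(key) {
    if (is.null(v@gt) || ncol(v@gt) < 2) return(rep(NA_character_, nrow(fix)))
    m <- suppressWarnings(
      vcfR::extract.gt(v, element = key, as.numeric = FALSE))
    if (is.null(m)) rep(NA_character_, nrow(fix)) else m[, 1L]
  }
  dp <- getFmt("DP"); dp[is.na(dp)] <- getInfo("DP")[is.na(dp)]
  af <- getFmt("AF"); af[is.na(af)] <- getFmt("VAF")[is.na(af)]
  af[is.na(af)] <- getInfo("AF")[is.na(af)]
  gt <- getFmt("GT")
  calls <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    depth = suppressWarnings(as.numeric(dp)),
    altFraction = af, genotype = gt, stringsAsFactors = FALSE)
  out <- splitMultiallelic(calls)
  out$altFraction <- suppressWarnings(as.numeric(out$altFraction))
  out
}

#' Write site-level variant calls to a VCF v4.2 file
#'
#' Emits one record per call with DP and AF in the INFO column and the
#' genotype (when present) in a single-sample GT column, so that
#' \code{\link{readVcfCalls}} round-trips the fields losslessly.
#'
#' @param calls data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{depth}, \code{altFraction}; optionally
#'   \code{genotype}.
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @return Invisibly, \code{path}.
#' @export
writeVcfCalls <- function(calls, path, sample = "sample1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alt allele fraction\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  gt <- if ("genotype" %in% names(calls)) {
    g <- as.character(calls$genotype); g[is.na(g)] <- "./."; g
  } else rep("./.", nrow(calls))
  info <- sprintf("DP=%s;AF=%s",
                  ifelse(is.na(calls$depth), ".",
                         format(calls$depth, trim = TRUE)),
                  ifelse(is.na(calls$altFraction), ".",
                         format(calls$altFraction, trim = TRUE,
                                digits = 10)))
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                "PASS", info, "GT", gt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
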