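#' Simulate low-pass pileup read counts over a marker panel
#'
#' Emulates the per-site evidence that alignment and pileup would produce
#' from a low-pass sequencing run: coverage at each site-by-individual cell
#' is Poisson with mean \code{meanDepth}, and each read reports the true
#' allele with probability \code{1 - errorRate} (a single symmetric base
#' error applied to both alleles). Heterozygotes transmit either allele
#' with probability 1/2 before the error is applied, so the alt-read
#' probability per genotype 0/1/2 is \code{errorRate}, 0.5,
#' \code{1 - errorRate}.
#'
#' @param panel a \code{\link{TruePanel}}.
#' @param meanDepth mean fold-coverage lambda (> 0).
#' @param errorRate per-read allele error epsilon in [0, 0.5).
#' @param seed integer seed.
#' @return A list with integer matrices \code{ref} and \code{alt}
#'   (markers x individuals) of read counts, and the realized
#'   \code{meanDepth}.
#' @examples
#' panel <- simulatePanel(5, 20, seed = 1)
#' pu <- simulatePileups(panel, meanDepth = 2, errorRate = 0.01, seed = 2)
#' range(pu$ref + pu$alt)
#' @export
simulatePileups <- function(panel, meanDepth, errorRate = 0.01, seed = 1L) {
  stopifnot(is(panel, "TruePanel"))
  assertScalarNumber(meanDepth, "meanDepth", lower = 1e-12)
  assertScalarNumber(errorRate, "errorRate", lower = 0, upper = 0.5 - 1e-12)

  g <- t(genotypes(panel))                       # markers x individuals
  set.seed(stageSeed(seed, "pileups"))
  cov <- matrix(rpois(length(g), meanDepth), nrow = nrow(g))
  pAlt <- matrix(c(errorRate, 0.5, 1 - errorRate)[g + 1L], nrow = nrow(g))
  alt <- matrix(rbinom(length(g), cov, pAlt), nrow = nrow(g))
  ref <- cov - alt
  dimnames(ref) <- dimnames(alt) <- dimnames(g)
  list(ref = ref, alt = alt, meanDepth = mean(cov))
}

#' Simulate aligned long reads with consistent CIGAR and NM
#'
#' Generates mapped SAM-style records against a given reference sequence,
#' injecting substitutions at \code{mismatchRate} per base and
#' single-base insertions/deletions at \code{indelRate} per base (split
#' evenly between the two). The emitted NM tag equals the injected
#' substitutions plus inserted plus deleted bases, and the CIGAR
#' query-consuming operation lengths sum to the sequence length. Per-read
#' truth (substitution and indel counts) is kept alongside for assertions.
#'
#' @param referenceSequence single character string of A/C/G/T.
#' @param nReads number of reads.
#' @param readLengthMean,readLengthSd,readLengthMin normal read-length
#'   model in bp, truncated below at \code{readLengthMin} (>= 1).
#' @param mismatchRate substitution probability per matched base.
#' @param indelRate indel event probability per base (events of length 1).
#' @param baseQuality constant per-base Phred quality written to QUAL.
#' @param chrom reference name used in RNAME.
#' @param seed integer seed.
#' @return A data.frame with SAM fields (\code{qname}, \code{flag},
#'   \code{rname}, \code{pos}, \code{mapq}, \code{cigar}, \code{seq},
#'   \code{qual}, \code{nm}) plus truth columns \code{queryLength},
#'   \code{trueSubstitutions}, \code{trueInsertedBases},
#'   \code{trueDeletedBases}, \code{refSpan}.
#' @seealso \code{\link{writeSam}}, \code{\link{readSamReads}}
#' @export
simulateSamReads <- function(referenceSequence, nReads = 100L,
                             readLengthMean = 1000, readLengthSd = 200,
                             readLengthMin = 200, mismatchRate = 0.01,
                             indelRate = 0.002, baseQuality = 20L,
                             chrom = "1", seed = 1L) {
  stopifnot(is.character(referenceSequence), length(referenceSequence) == 1L)
  refBases <- strsplit(toupper(referenceSequence), "")[[1]]
  refLen <- length(refBases)
  if (readLengthMin < 1) stop("readLengthMin must be >= 1")
  assertScalarNumber(mismatchRate, "mismatchRate", 0, 1)
  assertScalarNumber(indelRate, "indelRate", 0, 1)

  set.seed(stageSeed(seed, "reads"))
  lens <- pmax(round(rnorm(nReads, readLengthMean, readLengthSd)),
               readLengthMin)
  if (any(lens > refLen))
    stop("reference shorter than a requested read length")
  bases <- c("A", "C", "G", "T")

  one <- function(i) {
    L <- lens[i]
    # each query base is an inserted base w.p. indelRate/2; the rest align
    isIns <- runif(L) < indelRate / 2
    nM <- sum(!isIns)
    if (nM == 0L) { isIns[1L] <- FALSE; nM <- 1L }
    # deletions (ref bases skipped) occur after aligned bases
    delAfter <- runif(nM) < indelRate / 2
    nDel <- sum(delAfter)
    refSpan <- nM + nDel
    if (refSpan > refLen)
      stop("reference shorter than a requested read span")
    start <- sample.int(refLen - refSpan + 1L, 1L)

    # interleave ops in query order, with D ops spliced after their M base
    ops <- character(L + nDel)
    qOps <- ifelse(isIns, "I", "M")
    mSeen <- 0L; k <- 0L
    for (q in seq_len(L)) {
      k <- k + 1L; ops[k] <- qOps[q]
      if (qOps[q] == "M") {
        mSeen <- mSeen + 1L
        if (delAfter[mSeen]) { k <- k + 1L; ops[k] <- "D" }
      }
    }
    ops <- ops[seq_len(k)]

    refIdx <- start - 1L + cumsum(ops != "I")      # ref pointer per op
    seqChars <- character(length(ops))
    isSub <- logical(length(ops))
    for (j in seq_along(ops)) {
      if (ops[j] == "M") {
        b <- refBases[refIdx[j]]
        if (runif(1) < mismatchRate) {
          seqChars[j] <- sample(setdiff(bases, b), 1L)
          isSub[j] <- TRUE
        } else seqChars[j] <- b
      } else if (ops[j] == "I") {
        seqChars[j] <- sample(bases, 1L)
      }                                            # D consumes no query base
    }
    r <- rle(ops)
    cigar <- paste0(r$lengths, r$values, collapse = "")
    nSub <- sum(isSub)
    nIns <- sum(ops == "I")
    nDelB <- sum(ops == "D")
    data.frame(
      qname = sprintf("read%05d", i), flag = 0L, rname = chrom,
      pos = start, mapq = 60L, cigar = cigar,
      seq = paste0(seqChars[ops != "D"], collapse = ""),
      qual = strrep(rawToChar(as.raw(33L + baseQuality)), L),
      nm = nSub + nIns + nDelB,
      queryLength = L, trueSubstitutions = nSub,
      trueInsertedBases = nIns, trueDeletedBases = nDelB,
      refSpan = refSpan, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nReads), one))
  rownames(out) <- NULL
  out
}

#' Write simulated reads to a SAM file
#'
#' @param reads data.frame from \code{\link{simulateSamReads}}.
#' @param path output SAM path.
#' @param chrom,referenceLength reference name and length for the
#'   \code{@SQ} header line.
#' @return Invisibly, \code{path}.
#' @export
writeSam <- function(reads, path, chrom = "1", referenceLength) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(referenceLength)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  reads$mapq, reads$cigar, reads$seq, reads$qual, reads$nm)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a random reference sequence
#'
#' @param length reference length in bp.
#' @param seed integer seed.
#' @return A single character string of A/C/G/T.
#' @export
randomReference <- function(length, seed = 1L) {
  set.seed(stageSeed(seed, "reference"))
  paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE),
         collapse = "")
}
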