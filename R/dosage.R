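#' Posterior genotype distribution and allele dosage from read counts
#'
#' Per-site genotype inference from low-pass read counts: the prior over
#' genotypes 0/1/2 is Hardy-Weinberg at the population alternate-allele
#' frequency, \eqn{\{(1-p)^2, 2p(1-p), p^2\}}, and the likelihood is
#' binomial in the alt-read count with per-genotype alt-read
#' probabilities \eqn{\{\epsilon, 1/2, 1-\epsilon\}}. The dosage allele
#' (DA) is the posterior mean, a value in [0, 2]; sites with no reads
#' return the prior mean \eqn{2p}, so marker vectors stay complete. This
#' per-site posterior is the package's stand-in for reference-panel
#' haplotype imputation: it produces a DA with depth-dependent
#' uncertainty without modelling linkage disequilibrium.
#'
#' All arguments recycle to a common length.
#'
#' @param refCount,altCount non-negative read counts per site.
#' @param popAf population alternate-allele frequency in (0, 1).
#' @param errorRate per-read allele error in [0, 0.5).
#' @return A list: \code{posterior} (n x 3 matrix, columns \code{g0},
#'   \code{g1}, \code{g2}, rows summing to 1) and \code{dosage} (numeric
#'   in [0, 2]).
#' @examples
#' genotypePosterior(0, 0, popAf = 0.3)$dosage  # prior mean 0.6
#' @export
genotypePosterior <- function(refCount, altCount, popAf, errorRate = 0.01) {
  n <- max(length(refCount), length(altCount), length(popAf))
  refCount <- rep_len(refCount, n); altCount <- rep_len(altCount, n)
  popAf <- rep_len(popAf, n)
  if (any(refCount < 0 | altCount < 0))
    stop("read counts must be >= 0")
  if (any(popAf <= 0 | popAf >= 1))
    stop("popAf must lie strictly inside (0, 1)")
  assertScalarNumber(errorRate, "errorRate", 0, 0.5 - 1e-12)

  cov <- refCount + altCount
  prior <- cbind(g0 = (1 - popAf)^2, g1 = 2 * popAf * (1 - popAf),
                 g2 = popAf^2)
  pAlt <- c(errorRate, 0.5, 1 - errorRate)
  lik <- vapply(1:3, function(g) dbinom(altCount, cov, pAlt[g]), numeric(n))
  if (n == 1L) lik <- matrix(lik, nrow = 1L)
  post <- prior * lik
  post <- post / rowSums(post)
  colnames(post) <- c("g0", "g1", "g2")
  list(posterior = post, dosage = as.numeric(post[, 2L] + 2 * post[, 3L]))
}

#' Dosage matrix for a pileup set
#'
#' Applies \code{\link{genotypePosterior}} across a markers-by-individuals
#' pileup (as produced by \code{\link{simulatePileups}}), using the
#' panel's population allele frequency per marker.
#'
#' @param pileups list with \code{ref} and \code{alt} count matrices
#'   (markers x individuals).
#' @param popAf numeric vector of allele frequencies, one per marker.
#' @param errorRate per-read allele error.
#' @return Numeric dosage matrix (markers x individuals) in [0, 2].
#' @export
dosageMatrix <- function(pileups, popAf, errorRate = 0.01) {
  ref <- pileups$ref; alt <- pileups$alt
  stopifnot(identical(dim(ref), dim(alt)), length(popAf) == nrow(ref))
  gp <- genotypePosterior(as.vector(ref), as.vector(alt),
                          rep(popAf, times = ncol(ref)), errorRate)
  matrix(gp$dosage, nrow = nrow(ref), dimnames = dimnames(ref))
}

#' Call discrete genotypes from dosage alleles
#'
#' Heterozygous genotypes are called for dosages inside the het band
#' (inclusive at both ends, default [0.8, 1.2]); smaller dosages are
#' homozygous reference and larger dosages homozygous alternate.
#'
#' @param dosage numeric in [0, 2].
#' @param hetBand length-2 numeric, inclusive heterozygote band.
#' @return Integer genotype calls in \{0, 1, 2\}.
#' @examples
#' daToGenotype(c(0.79, 0.8, 1.2, 1.21))
#' @export
daToGenotype <- function(dosage, hetBand = c(0.8, 1.2)) {
  if (any(is.na(dosage)) || any(dosage < 0 | dosage > 2))
    stop("dosage must lie in [0, 2]")
  stopifnot(length(hetBand) == 2L, hetBand[1] <= hetBand[2])
  ifelse(dosage < hetBand[1], 0L,
         ifelse(dosage <= hetBand[2], 1L, 2L))
}

#' Genotype concordance against array genotypes
#'
#' Compares called genotypes with benchmark (array) genotypes site by
#' site. Each comparison falls into one of three categories by the
#' absolute difference of allele counts: correct (0), one-allele mismatch
#' (1) or both-alleles mismatch (2). Counts and proportions are reported
#' per true-genotype class together with the overall mismatch rate.
#'
#' @param called integer vector (or matrix) of called genotypes in 0:2.
#' @param true benchmark genotypes, same shape; when both carry names
#'   (or dimnames) they must agree, otherwise an error lists the
#'   offending sites.
#' @return A list: \code{counts} and \code{proportions} (3 x 3, true
#'   class x category), \code{mismatchRate} (overall fraction of
#'   discordant calls), \code{classMismatch} (per-class mismatch
#'   fraction, named \code{hom_ref}, \code{het}, \code{hom_alt}) and
#'   \code{n}.
#' @export
concordance <- function(called, true) {
  if (!is.null(names(called)) && !is.null(names(true))) {
    bad <- names(called) != names(true)
    if (any(bad))
      stop("site sets differ: ", paste(utils::head(names(called)[bad], 5),
                                       collapse = ", "))
  }
  called <- as.vector(called); true <- as.vector(true)
  if (length(called) != length(true))
    stop("called and true genotypes must have the same length")
  if (!all(called %in% 0:2) || !all(true %in% 0:2))
    stop("genotypes must be 0, 1 or 2")
  cat3 <- factor(abs(called - true), levels = 0:2,
                 labels = c("correct", "one_allele_mismatch",
                            "both_alleles_mismatch"))
  trueClass <- factor(true, levels = 0:2,
                      labels = c("hom_ref", "het", "hom_alt"))
  counts <- table(trueClass, cat3)
  props <- prop.table(counts + 0, margin = 1)
  classN <- rowSums(counts)
  classMis <- ifelse(classN > 0, 1 - counts[, "correct"] / classN, NA_real_)
  list(counts = counts, proportions = props,
       mismatchRate = mean(called != true),
       classMismatch = setNames(as.numeric(classMis), rownames(counts)),
       n = length(called))
}
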