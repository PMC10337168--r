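#' Subsample reads to a target sequencing depth
#'
#' Chooses reads uniformly without replacement so that the expected depth
#' of the subsample equals the target: the retained count is
#' \code{round(targetDepth / sourceDepth * n)}. Subsampling never
#' fabricates reads — the result is always a subset of the input.
#'
#' @param reads data.frame of reads (one row per read).
#' @param targetDepth desired fold-coverage, at most \code{sourceDepth}.
#' @param sourceDepth realized fold-coverage of \code{reads}.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return The subsampled data.frame.
#' @export
subsampleReads <- function(reads, targetDepth, sourceDepth, seed = 1L) {
  if (targetDepth > sourceDepth)
    stop("targetDepth exceeds sourceDepth")
  n <- nrow(reads)
  k <- round(targetDepth / sourceDepth * n)
  set.seed(stageSeed(seed, "titration"))
  reads[sort(sample.int(n, k)), , drop = FALSE]
}

#' Subsample pileup read counts to a target depth
#'
#' Treats every read in a per-individual pileup as a sampling unit and
#' keeps \code{round(targetDepth / sourceDepth * n)} of them uniformly
#' without replacement, so the per-site kept counts follow a multivariate
#' hypergeometric law — exactly what subsampling an alignment to a lower
#' depth does to its pileup.
#'
#' @param pileups list with \code{ref}/\code{alt} count matrices
#'   (markers x individuals), e.g. from \code{\link{simulatePileups}}.
#' @param targetDepth desired mean fold-coverage.
#' @param sourceDepth realized mean fold-coverage of the input; defaults
#'   to the mean of the summed count matrices.
#' @param seed integer seed.
#' @return A list with thinned \code{ref} and \code{alt} matrices and the
#'   realized \code{meanDepth}.
#' @export
subsamplePileups <- function(pileups, targetDepth, sourceDepth = NULL,
                             seed = 1L) {
  ref <- pileups$ref; alt <- pileups$alt
  if (is.null(sourceDepth)) sourceDepth <- mean(ref + alt)
  if (targetDepth > sourceDepth)
    stop("targetDepth exceeds sourceDepth")
  frac <- targetDepth / sourceDepth
  p <- nrow(ref)
  set.seed(stageSeed(seed, "titration"))
  for (j in seq_len(ncol(ref))) {
    counts <- c(ref[, j], alt[, j])            # 2p read categories
    n <- sum(counts)
    k <- round(frac * n)
    if (k >= n) next
    readCat <- rep.int(seq_along(counts), counts)
    kept <- tabulate(readCat[sample.int(n, k)], nbins = 2L * p)
    ref[, j] <- kept[seq_len(p)]
    alt[, j] <- kept[p + seq_len(p)]
  }
  list(ref = ref, alt = alt, meanDepth = mean(ref + alt))
}

#' Depth-titration of dosage and DGV performance
#'
#' Re-runs the dosage-to-DGV pipeline on read subsamples at a ladder of
#' target depths, mirroring the downsampling experiment in which reads
#' are randomly selected to reach 0.5x, 1.0x, 1.5x and 2.0x. For each
#' (depth, replicate) cell a fresh low-pass pileup is simulated at the
#' source depth, thinned to the target, converted to dosages under the
#' panel allele frequencies, and compared with the truth: DGV closeness
#' of dosage-based versus genotype-based values for \code{trait}, and
#' genotype concordance of the dosage calls.
#'
#' @param panel a \code{\link{TruePanel}}.
#' @param targetDepths fold-coverages to titrate (default 0.5, 1, 1.5, 2).
#' @param replicates replicate subsampling draws per depth.
#' @param errorRate per-read allele error used both in simulation and in
#'   the posterior.
#' @param sourceDepth depth the source pileups are simulated at; must be
#'   at least \code{max(targetDepths)}.
#' @param trait trait id used for the DGV closeness.
#' @param seed integer seed.
#' @return data.frame with one row per (depth, replicate):
#'   \code{depth}, \code{replicate}, \code{rSquared}, \code{slope},
#'   \code{intercept}, \code{spearman}, \code{hetMismatch},
#'   \code{homMismatch}, \code{mismatchRate}.
#' @export
titrationCurve <- function(panel, targetDepths = c(0.5, 1, 1.5, 2),
                           replicates = 1L, errorRate = 0.01,
                           sourceDepth = max(targetDepths),
                           trait = colnames(markerEffects(panel))[1L],
                           seed = 1L) {
  stopifnot(is(panel, "TruePanel"))
  if (any(targetDepths > sourceDepth))
    stop("targetDepths must not exceed sourceDepth")
  eff <- effectsTable(panel)
  truth <- genotypes(panel)
  dgvTrue <- computeDgv(truth, eff, trait)
  af <- alleleFreqs(panel)

  rows <- list()
  for (r in seq_len(replicates)) {
    repSeed <- stageSeed(seed, "titration") + r
    src <- simulatePileups(panel, sourceDepth, errorRate, seed = repSeed)
    for (d in targetDepths) {
      pu <- if (d >= src$meanDepth) src else
        subsamplePileups(src, d, src$meanDepth, seed = repSeed + 7919L * d)
      ds <- dosageMatrix(pu, af, errorRate)
      dgvLps <- computeDgv(t(ds), eff, trait)
      cl <- closeness(dgvTrue, dgvLps)
      cc <- concordance(daToGenotype(as.vector(ds)), as.vector(t(truth)))
      hom <- cc$counts[c("hom_ref", "hom_alt"), ]
      homMis <- 1 - sum(hom[, "correct"]) / sum(hom)
      rows[[length(rows) + 1L]] <- data.frame(
        depth = d, replicate = r,
        rSquared = cl$rSquared, slope = cl$slope,
        intercept = cl$intercept, spearman = cl$spearman,
        hetMismatch = cc$classMismatch[["het"]],
        homMismatch = homMis,
        mismatchRate = cc$mismatchRate)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate a titration table across replicates
#'
#' @param curve output of \code{\link{titrationCurve}}.
#' @return data.frame of per-depth means and (n-1) standard deviations of
#'   every metric.
#' @export
aggregateTitration <- function(curve) {
  metrics <- setdiff(names(curve), c("depth", "replicate"))
  m <- aggregate(curve[metrics], list(depth = curve$depth), mean)
  s <- aggregate(curve[metrics], list(depth = curve$depth), sd)
  names(m)[-1L] <- paste0(metrics, "Mean")
  names(s)[-1L] <- paste0(metrics, "Sd")
  merge(m, s, by = "depth")
}
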