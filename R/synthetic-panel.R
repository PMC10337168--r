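#' TruePanel: a simulated marker panel with known truth
#'
#' Container for a simulated population used as the ground truth behind the
#' low-pass genotyping evaluation: marker positions and alleles, population
#' allele frequencies, the individuals-by-markers genotype matrix (0/1/2
#' copies of the alternate allele, drawn under Hardy-Weinberg equilibrium)
#' and per-trait allele-substitution effects with intercepts. Genotypes
#' double as the "SNP array" benchmark for concordance and DGV closeness.
#'
#' @slot chrom single chromosome name all markers live on.
#' @slot genomeLength reference length in bp.
#' @slot positions strictly increasing 1-based marker positions.
#' @slot ref,alt reference / alternate allele per marker (A/C/G/T, ref != alt).
#' @slot alleleFreqs population alternate-allele frequency per marker,
#'   in (0, 1).
#' @slot genotypes integer matrix, individuals x markers, values in 0:2.
#' @slot intercepts named numeric, per-trait intercept (trait units).
#' @slot effects numeric matrix, markers x traits, allele-substitution
#'   effects (trait units per allele copy).
#'
#' @seealso \code{\link{simulatePanel}}
#' @export
setClass("TruePanel",
  representation(
    chrom        = "character",
    genomeLength = "integer",
    positions    = "integer",
    ref          = "character",
    alt          = "character",
    alleleFreqs  = "numeric",
    genotypes    = "matrix",
    intercepts   = "numeric",
    effects      = "matrix"
  )
)

setValidity("TruePanel", function(object) {
  msg <- character()
  p <- length(object@positions)
  if (length(object@chrom) != 1L)
    msg <- c(msg, "chrom must be a single name")
  if (any(diff(object@positions) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  if (p && (object@positions[1L] < 1L ||
            object@positions[p] > object@genomeLength))
    msg <- c(msg, "positions must lie within [1, genomeLength]")
  if (length(object@ref) != p || length(object@alt) != p)
    msg <- c(msg, "ref/alt must have one allele per marker")
  if (any(object@ref == object@alt))
    msg <- c(msg, "each marker must have ref != alt")
  if (length(object@alleleFreqs) != p ||
      any(object@alleleFreqs <= 0 | object@alleleFreqs >= 1))
    msg <- c(msg, "allele frequencies must be in (0, 1), one per marker")
  if (ncol(object@genotypes) != p)
    msg <- c(msg, "genotype matrix must have one column per marker")
  if (!all(object@genotypes %in% 0:2))
    msg <- c(msg, "genotypes must be 0, 1 or 2")
  if (nrow(object@effects) != p)
    msg <- c(msg, "effects must have one row per marker")
  if (ncol(object@effects) != length(object@intercepts))
    msg <- c(msg, "one intercept per trait column of effects")
  if (length(msg)) msg else TRUE
})

#' Accessors for TruePanel
#'
#' @param panel a \code{\link{TruePanel}}.
#' @return \code{snpPositions}: integer positions; \code{alleleFreqs}:
#'   numeric frequencies; \code{genotypes}: integer matrix (individuals x
#'   markers); \code{markerEffects}: numeric matrix (markers x traits);
#'   \code{traitIntercepts}: named numeric; \code{markerKeys}: character
#'   "chrom:pos:alt" keys; \code{markerInfo}: data.frame of chrom, pos,
#'   ref, alt, alleleFreq.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
snpPositions <- function(panel) panel@positions

#' @rdname panel-accessors
#' @export
nIndividuals <- function(panel) nrow(panel@genotypes)

#' @rdname panel-accessors
#' @export
nMarkers <- function(panel) length(panel@positions)

#' @rdname panel-accessors
#' @export
alleleFreqs <- function(panel) panel@alleleFreqs

#' @rdname panel-accessors
#' @export
genotypes <- function(panel) panel@genotypes

#' @rdname panel-accessors
#' @export
markerEffects <- function(panel) panel@effects

#' @rdname panel-accessors
#' @export
traitIntercepts <- function(panel) panel@intercepts

#' @rdname panel-accessors
#' @export
markerKeys <- function(panel)
  paste(panel@chrom, panel@positions, panel@alt, sep = ":")

#' @rdname panel-accessors
#' @export
markerInfo <- function(panel)
  data.frame(chrom = panel@chrom, pos = panel@positions,
             ref = panel@ref, alt = panel@alt,
             alleleFreq = panel@alleleFreqs,
             row.names = NULL, stringsAsFactors = FALSE)

setMethod("show", "TruePanel", function(object) {
  cat("TruePanel:", nrow(object@genotypes), "individuals x",
      length(object@positions), "markers on", object@chrom,
      sprintf("(%d bp)\n", object@genomeLength))
  cat("  MAF range:",
      sprintf("%.3f-%.3f", min(pmin(object@alleleFreqs,
                                    1 - object@alleleFreqs)),
              max(pmin(object@alleleFreqs, 1 - object@alleleFreqs))), "\n")
  cat("  traits:", paste(names(object@intercepts), collapse = ", "), "\n")
})

#' Simulate a marker panel with HWE genotypes and trait effects
#'
#' Draws marker positions uniformly (unique, strictly increasing) along a
#' single chromosome, alternate-allele frequencies uniformly on
#' \code{mafRange}, genotypes per site as Binomial(2, p) — i.e.
#' Hardy-Weinberg equilibrium with no linkage disequilibrium — and
#' per-trait allele-substitution effects from a zero-mean normal.
#'
#' @param nIndividuals number of individuals (>= 1).
#' @param nSnps number of markers (>= 1).
#' @param mafRange length-2 numeric, allele-frequency range in (0, 0.5].
#' @param genomeLength chromosome length in bp.
#' @param traits character vector of trait names.
#' @param effectSd standard deviation of the normal effects draw, per trait
#'   unit per allele copy.
#' @param intercepts optional named numeric of per-trait intercepts;
#'   defaults to 0 for every trait.
#' @param chrom chromosome name.
#' @param seed integer seed; identical seeds give identical panels.
#' @return A \code{\link{TruePanel}}.
#' @examples
#' panel <- simulatePanel(10, 50, seed = 1)
#' dim(genotypes(panel))
#' @export
simulatePanel <- function(nIndividuals, nSnps, mafRange = c(0.05, 0.5),
                          genomeLength = 1e6L, traits = c("MY", "FY", "PY"),
                          effectSd = 1, intercepts = NULL, chrom = "1",
                          seed = 1L) {
  if (!is.numeric(nIndividuals) || nIndividuals < 1)
    stop("nIndividuals must be >= 1")
  if (!is.numeric(nSnps) || nSnps < 1)
    stop("nSnps must be >= 1")
  if (length(mafRange) != 2L || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("mafRange must satisfy 0 < low <= high <= 0.5")
  if (genomeLength < nSnps)
    stop("genomeLength must allow nSnps unique positions")
  nIndividuals <- as.integer(nIndividuals)
  nSnps <- as.integer(nSnps)

  set.seed(stageSeed(seed, "panel"))
  positions <- sort(sample.int(as.integer(genomeLength), nSnps))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nSnps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  af <- runif(nSnps, mafRange[1], mafRange[2])
  geno <- matrix(rbinom(nIndividuals * nSnps, 2L, rep(af, each = nIndividuals)),
                 nrow = nIndividuals, ncol = nSnps)
  storage.mode(geno) <- "integer"
  effects <- matrix(rnorm(nSnps * length(traits), 0, effectSd),
                    nrow = nSnps, ncol = length(traits),
                    dimnames = list(NULL, traits))
  if (is.null(intercepts)) intercepts <- setNames(rep(0, length(traits)), traits)
  if (!all(traits %in% names(intercepts)))
    stop("intercepts must be named by trait")

  keys <- paste(chrom, positions, alt, sep = ":")
  dimnames(geno) <- list(paste0("ind", seq_len(nIndividuals)), keys)
  rownames(effects) <- keys

  new("TruePanel", chrom = chrom,
      genomeLength = as.integer(genomeLength),
      positions = as.integer(positions), ref = unname(ref), alt = unname(alt),
      alleleFreqs = af, genotypes = geno,
      intercepts = intercepts[traits], effects = effects)
}
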