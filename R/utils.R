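#' Derive a per-stage random seed from a global seed
#'
#' Expands one user-facing seed into independent substreams so that
#' pipeline stages (panel, reads, pileups, methylation, ...) can be
#' regenerated independently without sharing a random stream.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 1) or a known stage name.
#' @return An integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
  stages <- c(panel = 1L, pileups = 2L, reads = 3L, methylation = 4L,
              titration = 5L, genes = 6L, reference = 7L)
  if (is.character(stage)) {
    if (!stage %in% names(stages))
      stop("unknown stage name: ", stage)
    stage <- stages[[stage]]
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  # LCG-style mix; keeps the result a valid 32-bit R integer
  as.integer((as.double(seed) * 48271 + as.double(stage) * 16807) %% 2147483647)
}

# round half away from zero at `digits` decimals (matching how results
# tables are typically typeset, unlike banker's rounding in round())
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# truncate toward zero at `digits` decimals
truncateAt <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m) / m
}

#' Format a numeric value to fixed precision
#'
#' @param x numeric vector.
#' @param digits decimal places kept.
#' @param mode \code{"round"} (half away from zero) or \code{"truncate"}
#'   (toward zero). Both conventions occur in published summary tables.
#' @return Numeric vector at the requested precision.
#' @export
formatValue <- function(x, digits = 1L, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (mode == "round") roundHalfUp(x, digits) else truncateAt(x, digits)
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]",
                 name, format(lower), format(upper)))
  invisible(x)
}
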