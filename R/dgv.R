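#' Effects tables: per-trait intercepts and allele-substitution effects
#'
#' An effects table holds, for each trait, an intercept and one
#' allele-substitution effect per marker, with markers keyed by
#' chromosome, position and alternate allele. \code{effectsTable} builds
#' one from a \code{\link{TruePanel}}; \code{readEffectsTable} and
#' \code{writeEffectsTable} exchange the tab-separated representation
#' (columns trait, chrom, pos, ref, alt, beta, with per-trait intercepts
#' on \code{##intercept} header lines).
#'
#' @param panel a \code{\link{TruePanel}}.
#' @return A list with \code{markers} (data.frame: trait, chrom, pos,
#'   ref, alt, beta) and \code{intercepts} (named numeric).
#' @export
effectsTable <- function(panel) {
  info <- markerInfo(panel)
  eff <- markerEffects(panel)
  traits <- colnames(eff)
  markers <- do.call(rbind, lapply(traits, function(t)
    data.frame(trait = t, chrom = info$chrom, pos = info$pos,
               ref = info$ref, alt = info$alt, beta = eff[, t],
               row.names = NULL, stringsAsFactors = FALSE)))
  list(markers = markers, intercepts = traitIntercepts(panel))
}

#' @rdname effectsTable
#' @param effects an effects table (list of \code{markers} and
#'   \code{intercepts}).
#' @param path tab-separated file path.
#' @export
writeEffectsTable <- function(effects, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##intercept\t%s\t%.10g",
                     names(effects$intercepts), effects$intercepts), con)
  write.table(effects$markers, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname effectsTable
#' @export
readEffectsTable <- function(path) {
  lines <- readLines(path)
  ic <- grep("^##intercept\t", lines, value = TRUE)
  parts <- strsplit(ic, "\t", fixed = TRUE)
  intercepts <- setNames(vapply(parts, function(x) as.numeric(x[3]),
                                numeric(1)),
                         vapply(parts, `[`, character(1), 2L))
  markers <- read.delim(text = lines[!startsWith(lines, "##")],
                        stringsAsFactors = FALSE,
                        colClasses = c(chrom = "character"))
  list(markers = markers, intercepts = intercepts)
}

#' Direct genomic values from genotypes or dosages
#'
#' Computes, per individual, the linear genomic prediction
#' \deqn{DGV_{it} = \mu_t + \sum_j x_j \beta_{jt}} where \eqn{x_j} is the
#' marker value — an integer array genotype or a continuous dosage allele
#' in [0, 2] — and \eqn{\beta_{jt}} the allele-substitution effect of
#' marker \eqn{j} on trait \eqn{t}. Every marker in the trait's effects
#' must be present in \code{x}; missing markers are an error, never
#' silently zeroed. When marker ref/alt alleles are supplied alongside
#' \code{x} and a marker's alleles are swapped relative to the effects
#' table, its values are mirrored to \code{2 - x} (with a message giving
#' the flip count) before the linear combination.
#'
#' @param x numeric matrix (individuals x markers) with column names
#'   "chrom:pos:alt" marker keys, or a vector for a single individual
#'   with names.
#' @param effects an \code{\link{effectsTable}}.
#' @param trait trait id present in the effects.
#' @param markerAlleles optional data.frame (\code{key}, \code{ref},
#'   \code{alt}) describing the orientation of \code{x}'s markers, used
#'   to detect and mirror allele flips.
#' @return Named numeric vector of DGVs, one per individual.
#' @examples
#' eff <- list(markers = data.frame(trait = "MY", chrom = "1",
#'                                  pos = c(10, 20), ref = "A", alt = "T",
#'                                  beta = c(1.5, -0.5)),
#'             intercepts = c(MY = 0))
#' x <- matrix(c(2, 1), 1, dimnames = list("i1", c("1:10:T", "1:20:T")))
#' computeDgv(x, eff, "MY")  # 2.5
#' @export
computeDgv <- function(x, effects, trait, markerAlleles = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list("ind1", names(x)))
  em <- effects$markers[effects$markers$trait == trait, , drop = FALSE]
  if (!nrow(em)) stop("trait not present in effects: ", trait)
  if (!trait %in% names(effects$intercepts))
    stop("no intercept for trait: ", trait)
  keys <- paste(em$chrom, em$pos, em$alt, sep = ":")

  if (!is.null(markerAlleles)) {
    flippedKeys <- paste(em$chrom, em$pos, em$ref, sep = ":")
    hit <- match(keys, markerAlleles$key)
    flip <- match(flippedKeys, markerAlleles$key)
    useFlip <- is.na(hit) & !is.na(flip)
    if (any(useFlip)) {
      ok <- markerAlleles$ref[flip[useFlip]] == em$alt[useFlip] &
        markerAlleles$alt[flip[useFlip]] == em$ref[useFlip]
      useFlip[useFlip] <- ok
    }
    if (any(useFlip)) {
      message(sum(useFlip), " marker(s) with swapped ref/alt mirrored to 2-x")
      mk <- markerAlleles$key[flip[useFlip]]
      x[, mk] <- 2 - x[, mk, drop = FALSE]
      colnames(x)[match(mk, colnames(x))] <- keys[useFlip]
    }
  }

  missing <- setdiff(keys, colnames(x))
  if (length(missing))
    stop("markers in effects absent from input: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)",
                                           length(missing) - 10))
  if (any(x[, keys] < 0 | x[, keys] > 2, na.rm = TRUE))
    stop("marker values must lie in [0, 2]")
  dgv <- effects$intercepts[[trait]] +
    as.numeric(x[, keys, drop = FALSE] %*% em$beta)
  setNames(dgv, rownames(x))
}

#' Closeness between benchmark and low-pass DGVs
#'
#' Regresses the benchmark (SNP-array) DGVs on the low-pass DGVs —
#' benchmark is the response — and reports the regression R-squared,
#' intercept and slope, together with the Pearson and Spearman (average
#' ranks on ties) correlations. For simple OLS the R-squared equals the
#' squared Pearson correlation.
#'
#' @param benchmark,lps paired numeric vectors, length >= 3.
#' @return A list: \code{rSquared}, \code{intercept}, \code{slope},
#'   \code{pearson}, \code{spearman}, \code{n}. If either vector has zero
#'   variance the correlations and R-squared are \code{NA} with a
#'   warning.
#' @examples
#' closeness(c(5, 7, 9), c(1, 2, 3))  # slope 2, intercept 3, R2 1
#' @export
closeness <- function(benchmark, lps) {
  if (length(benchmark) != length(lps))
    stop("benchmark and lps must be paired vectors of equal length")
  n <- length(benchmark)
  if (n < 3) stop("at least 3 pairs are required")
  if (sd(benchmark) == 0 || sd(lps) == 0) {
    warning("zero variance: correlations undefined")
    return(list(rSquared = NA_real_, intercept = NA_real_,
                slope = NA_real_, pearson = NA_real_,
                spearman = NA_real_, n = n))
  }
  fit <- lm(benchmark ~ lps)
  # R^2 from residuals directly; summary.lm() warns on exact fits
  rsq <- 1 - sum(fit$residuals^2) / sum((benchmark - mean(benchmark))^2)
  list(rSquared = rsq,
       intercept = unname(coef(fit)[1L]),
       slope = unname(coef(fit)[2L]),
       pearson = cor(benchmark, lps),
       spearman = cor(benchmark, lps, method = "spearman"),
       n = n)
}
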