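#' Bundled per-sample sequencing summary
#'
#' Loads the per-sample summary table shipped with the package: 28
#' low-pass Holstein samples across three nanopore kits (LSK109, Q20,
#' LSK114) with sequencing depth (fold), genome breadth (percent of
#' positions covered) and number of variants called after filtering.
#'
#' @return data.frame with columns \code{sample}, \code{kit},
#'   \code{depth}, \code{breadth}, \code{nVariants}.
#' @export
kitSampleTable <- function() {
  read.delim(system.file("extdata", "kit_sample_summary.tsv",
                         package = "epiglows"),
             stringsAsFactors = FALSE)
}

#' Per-sample and per-kit sequencing summaries
#'
#' Aggregates per-sample results into group (kit) summaries: mean and
#' sample (n-1) standard deviation of sequencing depth and variant
#' count, with the group size. Standard deviations are reported as
#' \code{NA} for single-sample groups. Empty groups are dropped with a
#' warning.
#'
#' @param samples data.frame with columns \code{kit} (or the column
#'   named by \code{grouping}), \code{depth} and \code{nVariants}.
#' @param grouping name of the grouping column.
#' @return A list: \code{samples} (the input) and \code{groups}, a
#'   data.frame of \code{kit}, \code{n}, \code{meanDepth}, \code{sdDepth},
#'   \code{meanVariants}, \code{sdVariants}.
#' @examples
#' summarizeSamples(kitSampleTable())$groups
#' @export
summarizeSamples <- function(samples, grouping = "kit") {
  stopifnot(all(c(grouping, "depth", "nVariants") %in% names(samples)))
  g <- samples[[grouping]]
  empty <- setdiff(unique(g), g[!is.na(samples$depth)])
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  groups <- do.call(rbind, lapply(unique(g), function(k) {
    d <- samples[g == k, , drop = FALSE]
    n <- nrow(d)
    data.frame(kit = k, n = n,
               meanDepth = mean(d$depth),
               sdDepth = if (n >= 2) sd(d$depth) else NA_real_,
               meanVariants = mean(d$nVariants),
               sdVariants = if (n >= 2) sd(d$nVariants) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(samples = samples, groups = groups)
}

#' Run the evaluation pipeline end to end on synthetic data
#'
#' Orchestrates the stages on a simulated cohort: panel simulation,
#' aligned-read QC (accuracy from NM/CIGAR), pileup simulation, dosage
#' inference, DGV closeness, optional depth titration and optional
#' methylation analysis. The configuration is a named list (or a YAML
#' file with the same keys); all randomness flows from the single
#' \code{seed} through per-stage substreams, so two runs with the same
#' configuration give identical outputs and manifests.
#'
#' Required keys: \code{seed}, \code{nIndividuals}, \code{nSnps},
#' \code{depth}, \code{errorRate}. Optional: \code{mafRange},
#' \code{genomeLength}, \code{traits}, \code{titration} (list with
#' \code{depths}, \code{replicates}), \code{methylation} (list with
#' \code{nSites}, \code{meanCoverage}, \code{minCoverages}),
#' \code{reads} (list with \code{nReads}, \code{readLengthMean},
#' \code{mismatchRate}, \code{indelRate}), \code{outDir}.
#'
#' @param config named list or path to a YAML file.
#' @return A list with elements \code{panel}, \code{readqc},
#'   \code{dosages}, \code{dgv} (per-trait closeness), \code{titration}
#'   (if configured), \code{methylation} (if configured) and
#'   \code{manifest}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("seed", "nIndividuals", "nSnps", "depth", "errorRate")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("config is missing required field(s): ",
         paste(miss, collapse = ", "))
  cfg <- config
  cfg$mafRange <- cfg$mafRange %||% c(0.05, 0.5)
  cfg$genomeLength <- cfg$genomeLength %||% 1e6
  cfg$traits <- cfg$traits %||% c("MY", "FY", "PY")

  panel <- simulatePanel(cfg$nIndividuals, cfg$nSnps,
                         mafRange = as.numeric(cfg$mafRange),
                         genomeLength = cfg$genomeLength,
                         traits = cfg$traits, seed = cfg$seed)

  readqc <- NULL
  if (!is.null(cfg$reads)) {
    rcfg <- cfg$reads
    refLen <- max(5 * (rcfg$readLengthMean %||% 1000), 10000)
    ref <- randomReference(refLen, seed = cfg$seed)
    reads <- simulateSamReads(
      ref, nReads = rcfg$nReads %||% 200L,
      readLengthMean = rcfg$readLengthMean %||% 1000,
      mismatchRate = rcfg$mismatchRate %||% 0.01,
      indelRate = rcfg$indelRate %||% 0.002, seed = cfg$seed)
    tms <- computeTms(reads$nm, reads$trueInsertedBases,
                      reads$trueDeletedBases)
    acc <- readAccuracy(tms, reads$queryLength)
    readqc <- list(summary = summarizeAccuracy(acc),
                   coverage = coverageStats(reads$pos, reads$refSpan,
                                            refLen))
  }

  pu <- simulatePileups(panel, cfg$depth, cfg$errorRate, seed = cfg$seed)
  ds <- dosageMatrix(pu, alleleFreqs(panel), cfg$errorRate)
  eff <- effectsTable(panel)
  truth <- genotypes(panel)
  dgv <- lapply(cfg$traits, function(t) {
    closeness(computeDgv(truth, eff, t), computeDgv(t(ds), eff, t))
  })
  names(dgv) <- cfg$traits

  titration <- NULL
  if (!is.null(cfg$titration)) {
    titration <- titrationCurve(
      panel, targetDepths = as.numeric(cfg$titration$depths %||%
                                         c(0.5, 1, 1.5, 2)),
      replicates = cfg$titration$replicates %||% 1L,
      errorRate = cfg$errorRate, seed = cfg$seed)
  }

  methylation <- NULL
  if (!is.null(cfg$methylation)) {
    mcfg <- cfg$methylation
    sim <- simulateMethylation(mcfg$nSites %||% 10000L,
                               meanCoverage = mcfg$meanCoverage %||% 2,
                               seed = cfg$seed)
    thresholds <- as.integer(mcfg$minCoverages %||% c(4L, 7L, 10L))
    filtered <- lapply(thresholds, function(th)
      coverageFilter(sim$sites, th))
    names(filtered) <- paste0("cov", thresholds)
    methylation <- list(
      nSites = vapply(filtered, length, integer(1)),
      profiles = lapply(filtered, binMethylation))
  }

  manifest <- list(
    package = as.character(utils::packageVersion("epiglows")),
    config = cfg,
    stageSeeds = vapply(c("panel", "pileups", "reads", "methylation",
                          "titration"),
                        function(s) stageSeed(cfg$seed, s), integer(1)))

  out <- list(panel = panel, readqc = readqc, dosages = ds, dgv = dgv,
              titration = titration, methylation = methylation,
              manifest = manifest)
  if (!is.null(cfg$outDir)) writePipelineOutputs(out, cfg$outDir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$dosages,
              file.path(outDir, "dosages.tsv"), sep = "\t", quote = FALSE)
  dgv <- do.call(rbind, lapply(names(result$dgv), function(t)
    data.frame(trait = t, result$dgv[[t]][c("rSquared", "intercept",
                                            "slope", "pearson",
                                            "spearman", "n")])))
  write.table(dgv, file.path(outDir, "dgv_closeness.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(result$titration))
    write.table(result$titration, file.path(outDir, "titration.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
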