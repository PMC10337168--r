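#' Gene models for feature annotation
#'
#' A gene model bundles gene spans (with strand) and their exon
#' intervals; the transcription start site (TSS) of each gene is the
#' strand-appropriate end of its span. \code{geneModel} builds one from
#' ranges already in memory; \code{readGeneModelsGff} imports a GFF3/GTF
#' file (requires the \pkg{rtracklayer} package);
#' \code{simulateGeneModel} draws non-overlapping genes with random exon
#' structure for testing.
#'
#' @param genes \code{GRanges} of gene spans with strand and a
#'   \code{gene_id} metadata column.
#' @param exons \code{GRanges} of exons with a \code{gene_id} column
#'   matching \code{genes}; every exon must lie within its gene span.
#' @return A list of class \code{"GeneModel"} with elements \code{genes},
#'   \code{exons} and \code{tss} (\code{GRanges} of width-1 TSS
#'   positions).
#' @export
geneModel <- function(genes, exons) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRanges"),
            !is.null(genes$gene_id), !is.null(exons$gene_id))
  hit <- match(exons$gene_id, genes$gene_id)
  if (anyNA(hit)) stop("exon with unknown gene_id")
  within <- GenomicRanges::start(exons) >= GenomicRanges::start(genes)[hit] &
    GenomicRanges::end(exons) <= GenomicRanges::end(genes)[hit]
  if (!all(within)) stop("exons must lie within their gene span")
  plus <- as.character(GenomicRanges::strand(genes)) != "-"
  tssPos <- ifelse(plus, GenomicRanges::start(genes),
                   GenomicRanges::end(genes))
  tss <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(start = tssPos, width = 1L),
    strand = GenomicRanges::strand(genes),
    gene_id = genes$gene_id)
  structure(list(genes = genes, exons = exons, tss = tss),
            class = "GeneModel")
}

#' @rdname geneModel
#' @param path GFF3/GTF file with \code{gene} and \code{exon} features.
#' @export
readGeneModelsGff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("readGeneModelsGff requires the rtracklayer package")
  gff <- rtracklayer::import(path)
  genes <- gff[gff$type == "gene"]
  exons <- gff[gff$type == "exon"]
  gid <- if (!is.null(genes$ID)) genes$ID else genes$gene_id
  eid <- if (!is.null(exons$Parent))
    as.character(unlist(exons$Parent)) else exons$gene_id
  g <- GenomicRanges::granges(genes)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(gene_id = as.character(gid))
  e <- GenomicRanges::granges(exons)
  S4Vectors::mcols(e) <- S4Vectors::DataFrame(
    gene_id = sub("^(transcript|gene):", "", as.character(eid)))
  geneModel(g, e)
}

#' @rdname geneModel
#' @param nGenes number of genes to draw.
#' @param genomeLength chromosome length in bp.
#' @param geneLength mean gene length in bp.
#' @param exonsPerGene mean exon count per gene.
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @export
simulateGeneModel <- function(nGenes, genomeLength = 1e7L,
                              geneLength = 20000L, exonsPerGene = 5L,
                              chrom = "1", seed = 1L) {
  set.seed(stageSeed(seed, "genes"))
  # lay genes on a jittered grid so they never overlap
  slot <- genomeLength %/% nGenes
  if (slot <= geneLength * 2)
    stop("genomeLength too small for nGenes non-overlapping genes")
  lens <- pmax(200L, round(rnorm(nGenes, geneLength, geneLength / 4)))
  lens <- pmin(lens, slot - 100L)
  starts <- (seq_len(nGenes) - 1L) * slot +
    sample.int(slot %/% 4, nGenes, replace = TRUE)
  strand <- sample(c("+", "-"), nGenes, replace = TRUE)
  ids <- sprintf("gene%03d", seq_len(nGenes))
  genes <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts, width = lens),
    strand = strand, gene_id = ids)
  exList <- lapply(seq_len(nGenes), function(i) {
    k <- max(1L, rpois(1L, exonsPerGene))
    # partition the gene into 2k+1 blocks; odd blocks are exons
    cuts <- sort(sample.int(lens[i] - 1L, min(2L * k, lens[i] - 1L)))
    bounds <- c(0L, cuts, lens[i])
    es <- starts[i] + bounds[seq(1, length(bounds) - 1, by = 2)]
    ee <- starts[i] + bounds[seq(2, length(bounds), by = 2)] - 1L
    ok <- ee >= es
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(start = es[ok], end = ee[ok]),
                           strand = strand[i], gene_id = ids[i])
  })
  exons <- do.call(c, exList)
  # guarantee the first exon starts at the gene start (a real gene's
  # first exon contains the TSS)
  geneModel(genes, exons)
}

#' Annotate methylation sites with genomic features
#'
#' Assigns each site the first matching category in priority order:
#' \emph{Promoter} (within the promoter window, default +/- 3,000 bp of
#' any TSS), \emph{Exon}, \emph{Intron} (inside a gene span but not an
#' exon), \emph{Downstream} (within \code{downstreamWindow} bp past the
#' strand-appropriate gene end) and \emph{Distal Intergenic}. Sites on a
#' chromosome absent from the model fall to Distal Intergenic and are
#' counted in the \code{unplacedChrom} attribute.
#'
#' @param sites \code{GRanges} of methylation sites.
#' @param model a \code{\link{geneModel}}.
#' @param promoterWindow half-width of the promoter window around the
#'   TSS, in bp.
#' @param downstreamWindow extent of the downstream region past the gene
#'   end, in bp.
#' @return Factor of categories, one per site, with levels Promoter,
#'   Exon, Intron, Downstream, \code{Distal Intergenic}.
#' @export
annotateFeature <- function(sites, model, promoterWindow = 3000L,
                            downstreamWindow = 3000L) {
  stopifnot(inherits(model, "GeneModel"))
  n <- length(sites)
  levs <- c("Promoter", "Exon", "Intron", "Downstream", "Distal Intergenic")
  known <- as.character(GenomicRanges::seqnames(sites)) %in%
    as.character(GenomicRanges::seqnames(model$genes))

  tssPos <- GenomicRanges::start(model$tss)
  promoters <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(model$tss),
    IRanges::IRanges(start = pmax(tssPos - promoterWindow, 1L),
                     end = tssPos + promoterWindow))
  # cross-chromosome sites are handled explicitly below, so the
  # seqlevel mismatch warning from the overlap machinery is noise here
  inProm <- suppressWarnings(
    IRanges::overlapsAny(sites, promoters, ignore.strand = TRUE))
  inExon <- suppressWarnings(
    IRanges::overlapsAny(sites, model$exons, ignore.strand = TRUE))
  inGene <- suppressWarnings(
    IRanges::overlapsAny(sites, model$genes, ignore.strand = TRUE))
  plus <- as.character(GenomicRanges::strand(model$genes)) != "-"
  dsStart <- ifelse(plus, GenomicRanges::end(model$genes) + 1L,
                    GenomicRanges::start(model$genes) - downstreamWindow)
  downstream <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(model$genes),
    IRanges::IRanges(start = pmax(dsStart, 1L), width = downstreamWindow))
  inDown <- suppressWarnings(
    IRanges::overlapsAny(sites, downstream, ignore.strand = TRUE))

  cat <- rep("Distal Intergenic", n)
  cat[inDown] <- "Downstream"
  cat[inGene & !inExon] <- "Intron"
  cat[inExon] <- "Exon"
  cat[inProm] <- "Promoter"
  cat[!known] <- "Distal Intergenic"
  structure(factor(cat, levels = levs),
            unplacedChrom = sum(!known))
}

#' Percentage breakdown of methylated sites by feature
#'
#' @param categories factor from \code{\link{annotateFeature}}.
#' @return data.frame of \code{category}, \code{count}, \code{percent};
#'   percentages sum to 100.
#' @export
featureBreakdown <- function(categories) {
  tab <- table(categories)
  data.frame(category = names(tab),
             count = as.integer(tab),
             percent = 100 * as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Density profile of methylated sites around the TSS
#'
#' Computes the strand-aware signed distance of each site to its nearest
#' TSS (negative = upstream of the TSS) and bins sites within
#' \code{+/- window} bp into \code{profileBin}-bp bins. The returned
#' density is normalized to sum to 1 over the bins.
#'
#' @param sites \code{GRanges} of methylation sites.
#' @param model a \code{\link{geneModel}}.
#' @param window half-width of the profile in bp.
#' @param profileBin bin width in bp.
#' @return data.frame with \code{binStart}, \code{binEnd} (signed
#'   distances), \code{count} and \code{density}. Zero sites within the
#'   window yields an empty data.frame with a warning.
#' @export
tssProfile <- function(sites, model, window = 3000L, profileBin = 50L) {
  stopifnot(inherits(model, "GeneModel"), window > 0, profileBin > 0)
  near <- suppressWarnings(
    GenomicRanges::distanceToNearest(sites, model$tss,
                                     ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(near); si <- S4Vectors::subjectHits(near)
  raw <- GenomicRanges::start(sites)[qi] -
    GenomicRanges::start(model$tss)[si]
  minus <- as.character(GenomicRanges::strand(model$tss))[si] == "-"
  signedDist <- ifelse(minus, -raw, raw)
  signedDist <- signedDist[abs(signedDist) <= window]
  breaks <- seq(-window, window, by = profileBin)
  if (breaks[length(breaks)] < window) breaks <- c(breaks, window)
  if (!length(signedDist)) {
    warning("no sites within the TSS window")
    return(data.frame(binStart = breaks[-length(breaks)],
                      binEnd = breaks[-1L],
                      count = 0L, density = NA_real_))
  }
  idx <- pmin(findInterval(signedDist, breaks), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(binStart = breaks[-length(breaks)], binEnd = breaks[-1L],
             count = counts, density = counts / sum(counts))
}
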