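mkSites <- function(pos, coverage, percent, chrom = "1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L),
                         strand = "+", coverage = coverage,
                         percentModified = percent)
}

test_that("coverage filter boundary is inclusive and thresholds nest", {
  gr <- mkSites(1:5, coverage = c(3, 4, 7, 9, 10), percent = 50)
  expect_equal(GenomicRanges::start(coverageFilter(gr, 4)), 2:5)
  expect_equal(GenomicRanges::start(coverageFilter(gr, 10)), 5L)

  sim <- simulateMethylation(3000, meanCoverage = 6, seed = 91)
  s4 <- coverageFilter(sim$sites, 4)
  s7 <- coverageFilter(sim$sites, 7)
  s10 <- coverageFilter(sim$sites, 10)
  expect_true(all(GenomicRanges::start(s7) %in% GenomicRanges::start(s4)))
  expect_true(all(GenomicRanges::start(s10) %in% GenomicRanges::start(s7)))
  expect_true(length(s4) >= length(s7) && length(s7) >= length(s10))
  expect_error(coverageFilter(gr, 0), "positive")
})

test_that("bin methylation is the coverage-weighted mean per 500-bp bin", {
  one <- binMethylation(mkSites(100, 5, 60))
  expect_equal(one$meanPercent, 60)
  expect_equal(one$binStart, 0L)

  two <- binMethylation(mkSites(c(100, 200), c(5, 5), c(0, 100)))
  expect_equal(two$meanPercent, 50)

  # weighting by coverage
  w <- binMethylation(mkSites(c(100, 200), c(9, 1), c(0, 100)))
  expect_equal(w$meanPercent, 10)

  set.seed(92)
  pos <- sample.int(50000, 400)
  cov <- rpois(400, 5) + 1L
  pct <- runif(400, 0, 100)
  got <- binMethylation(mkSites(pos, cov, pct), binWidth = 500)
  want <- bruteBinMeans(pos, cov, pct, 500)
  expect_equal(got$meanPercent, unname(want), tolerance = 1e-12)
  expect_error(binMethylation(mkSites(1, 1, 1), binWidth = 0), "positive")
})

test_that("filter agreement is Pearson over shared bins", {
  a <- binMethylation(mkSites(c(100, 600, 1100, 1600), 5, c(10, 40, 70, 90)))
  expect_equal(filterAgreement(a, a)$correlation, 1)

  b <- a; b$meanPercent <- 100 - b$meanPercent
  expect_equal(filterAgreement(a, b)$correlation, -1)

  small <- a[1:2, ]
  expect_warning(fa <- filterAgreement(small, small), "shared bins")
  expect_true(is.na(fa$correlation))

  # shared truth at lambda = 12: profiles under >=4x and >=10x agree
  sim <- simulateMethylation(10000, meanCoverage = 12, seed = 93)
  p4 <- binMethylation(coverageFilter(sim$sites, 4))
  p10 <- binMethylation(coverageFilter(sim$sites, 10))
  ag <- filterAgreement(p4, p10)
  expect_gt(ag$correlation, 0.9)
  expect_gte(ag$nShared, 3)
})

test_that("feature annotation follows the priority order and matches a brute scan", {
  genes <- GenomicRanges::GRanges("1",
    IRanges::IRanges(start = c(10000, 50000), end = c(30000, 70000)),
    strand = c("+", "-"), gene_id = c("gA", "gB"))
  exons <- GenomicRanges::GRanges("1",
    IRanges::IRanges(start = c(10000, 25000, 69000),
                     end = c(12000, 30000, 70000)),
    strand = c("+", "+", "-"), gene_id = c("gA", "gA", "gB"))
  model <- geneModel(genes, exons)

  # TSS of gA is 10000 (+); of gB is 70000 (-)
  site <- function(p) mkSites(p, 5, 50)
  expect_equal(as.character(annotateFeature(site(10000), model)), "Promoter")
  # 3,001 bp upstream of the only nearby TSS, outside genes -> distal
  expect_equal(as.character(annotateFeature(site(6999), model)),
               "Distal Intergenic")
  expect_equal(as.character(annotateFeature(site(7000), model)), "Promoter")
  # inside an exon 10+ kb from any TSS, priority gives Exon over Intron
  expect_equal(as.character(annotateFeature(site(26000), model)), "Exon")
  expect_equal(as.character(annotateFeature(site(20000), model)), "Intron")
  # downstream: past the + gene end within 3 kb
  expect_equal(as.character(annotateFeature(site(31000), model)),
               "Downstream")
  # unknown chromosome falls to distal with a logged count
  off <- annotateFeature(mkSites(100, 5, 50, chrom = "chr9"), model)
  expect_equal(as.character(off), "Distal Intergenic")
  expect_equal(attr(off, "unplacedChrom"), 1L)

  # random sites against the brute-force interval scan
  gm <- simulateGeneModel(12, genomeLength = 1e6, geneLength = 15000,
                          seed = 94)
  set.seed(95)
  pos <- sample.int(1e6, 2000)
  got <- as.character(annotateFeature(mkSites(pos, 5, 50), gm))
  want <- vapply(pos, bruteAnnotate, character(1), model = gm)
  expect_equal(got, want)
})

test_that("feature breakdown percentages sum to 100", {
  gm <- simulateGeneModel(8, genomeLength = 5e5, geneLength = 10000,
                          seed = 96)
  sim <- simulateMethylation(2000, meanCoverage = 5, genomeLength = 5e5,
                             seed = 97)
  bd <- featureBreakdown(annotateFeature(sim$sites, gm))
  expect_equal(sum(bd$percent), 100, tolerance = 0.01)
  expect_equal(sum(bd$count), length(sim$sites))
})

test_that("TSS profile is strand-aware, windowed and normalized", {
  genes <- GenomicRanges::GRanges("1",
    IRanges::IRanges(start = c(20000, 60000), end = c(30000, 70000)),
    strand = c("+", "-"), gene_id = c("gA", "gB"))
  exons <- GenomicRanges::GRanges("1",
    IRanges::IRanges(start = c(20000, 60000), end = c(21000, 61000)),
    strand = c("+", "-"), gene_id = c("gA", "gB"))
  model <- geneModel(genes, exons)

  # sites exactly at the TSSs all land in the central bin
  atTss <- mkSites(c(20000, 70000), 5, 50)
  prof <- tssProfile(atTss, model, window = 3000, profileBin = 50)
  expect_equal(sum(prof$density), 1)
  central <- prof$count[prof$binStart <= 0 & prof$binEnd > 0]
  expect_equal(sum(central), 2L)

  # upstream site of a minus-strand gene has positive (downstream) sign
  up <- mkSites(70100, 5, 50)   # 100 bp beyond the gB TSS, upstream in genome
  profUp <- tssProfile(up, model, window = 3000, profileBin = 50)
  expect_equal(profUp$count[profUp$binStart == -100], 1L)

  # roughly flat for uniform sites around uniform TSSs
  gm <- simulateGeneModel(20, genomeLength = 2e6, geneLength = 10000,
                          seed = 98)
  set.seed(99)
  sites <- mkSites(sort(sample.int(2e6, 20000)), 5, 50)
  flat <- tssProfile(sites, gm, window = 3000, profileBin = 500)
  expect_equal(sum(flat$density), 1)
  expect_lt(max(flat$density) / max(mean(flat$density), 1e-9), 2)

  expect_warning(empty <- tssProfile(mkSites(1, 5, 50, chrom = "chrZ"),
                                     model),
                 "no sites")
  expect_equal(sum(empty$count), 0L)
})
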