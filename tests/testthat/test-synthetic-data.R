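test_that("simulatePanel respects its configuration and is deterministic", {
  p1 <- simulatePanel(20, 10, mafRange = c(0.5, 0.5), seed = 11)
  expect_true(all(alleleFreqs(p1) == 0.5))

  p2 <- simulatePanel(20, 10, mafRange = c(0.5, 0.5), seed = 11)
  expect_identical(genotypes(p1), genotypes(p2))
  expect_identical(markerEffects(p1), markerEffects(p2))

  expect_true(all(diff(snpPositions(p1)) > 0))
  expect_true(all(genotypes(p1) %in% 0:2))
  info <- markerInfo(p1)
  expect_true(all(info$ref != info$alt))

  expect_error(simulatePanel(10, 10, mafRange = c(0, 0.5)), "mafRange")
  expect_error(simulatePanel(0, 10), "nIndividuals")
})

test_that("HWE genotype proportions match the binomial law at p = 0.5", {
  n <- 10000L
  panel <- simulatePanel(n, 1, mafRange = c(0.5, 0.5), seed = 42)
  g <- as.vector(genotypes(panel))
  props <- tabulate(g + 1L, 3L) / n
  expected <- c(0.25, 0.5, 0.25)
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(props - expected) < 3 * se))
})

test_that("pileup counts follow the stated Poisson/binomial model", {
  # epsilon = 0 and genotype 0 never produces an alt read
  panel0 <- simulatePanel(10, 50, mafRange = c(0.05, 0.1), seed = 3)
  g <- genotypes(panel0)
  pu0 <- simulatePileups(panel0, meanDepth = 3, errorRate = 0, seed = 4)
  hom0 <- t(g) == 0L
  expect_true(all(pu0$alt[hom0] == 0L))

  # mean coverage matches lambda within 3 standard errors at 10,000 draws
  panel <- simulatePanel(100, 100, seed = 5)
  pu <- simulatePileups(panel, meanDepth = 2, errorRate = 0.01, seed = 6)
  cov <- pu$ref + pu$alt
  n <- length(cov)
  expect_lt(abs(mean(cov) - 2), 3 * sqrt(2 / n))

  # heterozygote alt fraction converges to 0.5 without error
  panelHet <- simulatePanel(2000, 1, mafRange = c(0.5, 0.5), seed = 7)
  puHet <- simulatePileups(panelHet, meanDepth = 30, errorRate = 0, seed = 8)
  het <- t(genotypes(panelHet)) == 1L
  altFrac <- sum(puHet$alt[het]) / sum((puHet$ref + puHet$alt)[het])
  expect_lt(abs(altFrac - 0.5), 3 * sqrt(0.25 / sum((puHet$ref + puHet$alt)[het])))
})

test_that("simulated SAM reads carry self-consistent CIGAR and NM", {
  ref <- randomReference(30000, seed = 9)
  reads <- simulateSamReads(ref, nReads = 60, readLengthMean = 800,
                            readLengthSd = 150, readLengthMin = 200,
                            mismatchRate = 0.02, indelRate = 0.004,
                            seed = 10)
  refChars <- strsplit(ref, "")[[1]]

  # NM recomputed by brute-force base-by-base comparison equals the tag
  nmOracle <- mapply(recountEdits, reads$pos, reads$cigar, reads$seq,
                     MoreArgs = list(refChars = refChars))
  expect_equal(unname(nmOracle), reads$nm)
  expect_equal(reads$nm, reads$trueSubstitutions +
                 reads$trueInsertedBases + reads$trueDeletedBases)

  # query-consuming CIGAR lengths sum to the sequence length
  qlen <- vapply(reads$cigar, function(cg) {
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[A-Z]", cg))[[1]]
    sum(lens[ops %in% c("M", "I", "S")])
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(qlen, nchar(reads$seq))
  expect_equal(qlen, reads$queryLength)

  # error-free reads have NM = 0 and a single match operation
  clean <- simulateSamReads(ref, nReads = 10, mismatchRate = 0,
                            indelRate = 0, seed = 11)
  expect_true(all(clean$nm == 0L))
  expect_true(all(grepl("^[0-9]+M$", clean$cigar)))

  expect_error(simulateSamReads("ACGT", nReads = 1, readLengthMean = 100,
                                readLengthSd = 0, readLengthMin = 50),
               "reference shorter")
})

test_that("SAM writing round-trips through the reader", {
  ref <- randomReference(20000, seed = 12)
  reads <- simulateSamReads(ref, nReads = 30, mismatchRate = 0.01,
                            indelRate = 0.002, seed = 13)
  f <- tempfile(fileext = ".sam")
  writeSam(reads, f, chrom = "1", referenceLength = 20000)
  back <- readSamReads(f)
  expect_equal(nrow(back), nrow(reads))
  expect_equal(back$nm, reads$nm)
  expect_equal(back$queryLength, reads$queryLength)
  expect_equal(back$insertionLength, reads$trueInsertedBases)
  expect_equal(back$deletionLength, reads$trueDeletedBases)
  expect_true(all(back$mapped))
})

test_that("methylation simulator obeys its binomial/Poisson structure", {
  sim <- simulateMethylation(5000, meanCoverage = 2, seed = 14)
  expect_true(all(sim$truth$modified <= sim$truth$coverage))
  expect_true(all(sim$truth$trueLevel >= 0 & sim$truth$trueLevel <= 1))
  # zero-coverage sites are omitted from emitted records
  expect_equal(length(sim$sites), sum(sim$truth$coverage >= 1))

  # fully methylated truth gives 100 percent everywhere
  sat <- simulateMethylation(200, meanCoverage = 5, hyperWeight = 1,
                             hyperShape = c(1e6, 1e-6), seed = 15)
  expect_true(all(sat$sites$percentModified > 99.9))

  # coverage >= 4 fraction matches the Poisson tail at lambda = 2
  tail4 <- mean(sim$truth$coverage >= 4)
  expected <- ppois(3, 2, lower.tail = FALSE)
  n <- nrow(sim$truth)
  expect_lt(abs(tail4 - expected), 3 * sqrt(expected * (1 - expected) / n))

  # binomial oracle: percent near 100*level at huge coverage
  big <- simulateMethylation(50, meanCoverage = 10000, hyperWeight = 1,
                             hyperShape = c(5, 5), seed = 16)
  expect_true(all(abs(big$sites$percentModified -
                        100 * big$sites$trueLevel) <
                    3 * 100 * sqrt(0.25 / 9000)))
})

test_that("bedMethyl files round-trip and identical seeds give identical files", {
  sim <- simulateMethylation(300, meanCoverage = 3, seed = 17)
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  writeBedMethyl(sim$sites, f1)
  writeBedMethyl(simulateMethylation(300, meanCoverage = 3, seed = 17)$sites,
                 f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- readBedMethyl(f1)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(sim$sites))
  expect_equal(back$coverage, sim$sites$coverage)
  expect_equal(back$percentModified, round(sim$sites$percentModified, 2))
})
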