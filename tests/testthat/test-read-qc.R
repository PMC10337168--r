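test_that("read filter applies the length and quality boundaries", {
  rd <- data.frame(queryLength = c(150, 151, 10000, 5000),
                   meanQuality = c(20, 10, 9.99, NA))
  out <- filterReads(rd)
  # length exactly 150 is discarded, length 151 at quality 10 retained,
  # quality 9.99 discarded, missing quality treated as failing
  expect_equal(out$reads$queryLength, 151)
  expect_equal(unname(out$counts["retained"]), 1L)
  expect_equal(unname(out$counts["tooShort"]), 1L)
  expect_equal(unname(out$counts["lowQuality"]), 1L)
  expect_equal(unname(out$counts["missingQuality"]), 1L)
  expect_equal(sum(out$counts), nrow(rd))
})

test_that("TMS subtracts indel lengths from NM and clamps at zero", {
  expect_equal(computeTms(10, 3, 2), 5L)
  expect_equal(computeTms(0, 0, 0), 0L)
  expect_equal(computeTms(2, 3, 2), 0L)   # NM dialect below indel total
  expect_equal(computeTms(c(10, 0), c(3, 0), c(2, 0)), c(5L, 0L))
})

test_that("accuracy is 1 - TMS/length with domain checks", {
  expect_equal(readAccuracy(5, 1000), 0.995)
  expect_equal(readAccuracy(0, 123), 1)
  expect_equal(readAccuracy(0, 99999), 1)
  expect_error(readAccuracy(10, 5), "exceeds read length")
  expect_error(readAccuracy(-1, 5), ">= 0")
})

test_that("TMS on simulated reads equals the injected substitution count", {
  ref <- randomReference(30000, seed = 21)
  reads <- simulateSamReads(ref, nReads = 80, mismatchRate = 0.02,
                            indelRate = 0.005, seed = 22)
  tms <- computeTms(reads$nm, reads$trueInsertedBases,
                    reads$trueDeletedBases)
  expect_equal(tms, reads$trueSubstitutions)
})

test_that("mean accuracy of indel-free reads estimates the error rate", {
  eps <- 0.02
  ref <- randomReference(60000, seed = 23)
  reads <- simulateSamReads(ref, nReads = 200, readLengthMean = 2000,
                            readLengthSd = 100, mismatchRate = eps,
                            indelRate = 0, seed = 24)
  acc <- readAccuracy(computeTms(reads$nm, 0, 0), reads$queryLength)
  totalBases <- sum(reads$queryLength)
  se <- sqrt(eps * (1 - eps) / totalBases)
  expect_lt(abs(sum(reads$trueSubstitutions) / totalBases - eps), 3 * se)
  expect_lt(abs(mean(1 - acc) - eps), 3 * se * 3)  # per-read mean, wider
})

test_that("accuracy summary: median, binned mode and tie-breaking", {
  s1 <- summarizeAccuracy(0.99)
  expect_equal(s1$median, 0.99)
  expect_equal(s1$mode, 0.99, tolerance = 0.001)

  expect_equal(summarizeAccuracy(c(0.98, 0.99, 1.00))$median, 0.99)

  # mode equals the brute-force argmax over the same histogram
  set.seed(25)
  acc <- pmin(pmax(c(rnorm(6000, 0.99, 0.004), rnorm(4000, 0.95, 0.01)),
                   0), 1)
  s <- summarizeAccuracy(acc, binWidth = 0.001)
  breaks <- seq(0, 1, by = 0.001)
  counts <- vapply(seq_len(length(breaks) - 1L), function(i) {
    if (i < length(breaks) - 1L)
      sum(acc >= breaks[i] & acc < breaks[i + 1L])
    else sum(acc >= breaks[i] & acc <= breaks[i + 1L])
  }, integer(1))
  best <- max(which(counts == max(counts)))
  expect_equal(s$mode, (breaks[best] + breaks[best + 1L]) / 2)
  expect_equal(sum(s$histogram$count), length(acc))

  # ties break toward the higher-accuracy bin
  tie <- c(0.9501, 0.9902)
  expect_equal(summarizeAccuracy(tie)$mode, 0.9905, tolerance = 1e-9)

  expect_error(summarizeAccuracy(numeric(0)), "at least one")
})

test_that("coverage depth and breadth match a per-position pileup", {
  cs <- coverageStats(start = 1, refSpan = 100, referenceLength = 1000)
  expect_equal(cs$meanDepth, 0.1)
  expect_equal(cs$breadth, 10)

  cs2 <- coverageStats(start = c(1, 1), refSpan = c(100, 100),
                       referenceLength = 1000)
  expect_equal(cs2$meanDepth, 0.2)
  expect_equal(cs2$breadth, 10)

  set.seed(26)
  start <- sample.int(900, 50, replace = TRUE)
  span <- sample(20:100, 50, replace = TRUE)
  got <- coverageStats(start, span, 1000)
  want <- bruteCoverage(start, span, 1000)
  expect_equal(got$meanDepth, want$meanDepth)
  expect_equal(got$breadth, want$breadth)

  expect_error(coverageStats(1, 10, 0), "referenceLength")
})
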