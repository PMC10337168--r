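# Independent brute-force oracles used to check the package's fast paths.

# Recount a read's edit distance base by base against the reference by
# walking its CIGAR: mismatching M bases + inserted bases + deleted bases.
recountEdits <- function(pos, cigar, seq, refChars) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  qChars <- strsplit(seq, "")[[1]]
  ri <- pos; qi <- 1L; nm <- 0L
  for (k in seq_along(ops)) {
    L <- lens[k]
    if (ops[k] %in% c("M", "=", "X")) {
      for (b in seq_len(L)) {
        if (qChars[qi] != refChars[ri]) nm <- nm + 1L
        qi <- qi + 1L; ri <- ri + 1L
      }
    } else if (ops[k] == "I") {
      nm <- nm + L; qi <- qi + L
    } else if (ops[k] == "D") {
      nm <- nm + L; ri <- ri + L
    } else if (ops[k] == "S") {
      qi <- qi + L
    }
  }
  nm
}

# Per-position pileup coverage by explicit counting.
bruteCoverage <- function(start, refSpan, referenceLength) {
  depth <- integer(referenceLength)
  for (i in seq_along(start)) {
    idx <- start[i]:(start[i] + refSpan[i] - 1L)
    depth[idx] <- depth[idx] + 1L
  }
  list(meanDepth = sum(depth) / referenceLength,
       breadth = 100 * mean(depth >= 1))
}

# Genotype posterior by direct enumeration over g in {0,1,2}.
bruteBayes <- function(refCount, altCount, p, eps) {
  prior <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  pAlt <- c(eps, 0.5, 1 - eps)
  cov <- refCount + altCount
  lik <- vapply(1:3, function(g)
    choose(cov, altCount) * pAlt[g]^altCount * (1 - pAlt[g])^refCount,
    numeric(1))
  post <- prior * lik
  post <- post / sum(post)
  list(posterior = post, dosage = post[2] + 2 * post[3])
}

# Closeness statistics from their definitional formulas.
bruteCloseness <- function(y, x) {
  n <- length(y)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  pearson <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rx <- rank(x); ry <- rank(y)
  spearman <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  list(rSquared = pearson^2, intercept = intercept, slope = slope,
       pearson = pearson, spearman = spearman)
}

# Feature category of a single position by scanning every interval.
bruteAnnotate <- function(posn, model, promW = 3000L, downW = 3000L) {
  gs <- GenomicRanges::start(model$genes)
  ge <- GenomicRanges::end(model$genes)
  strand <- as.character(GenomicRanges::strand(model$genes))
  tss <- ifelse(strand != "-", gs, ge)
  if (any(abs(posn - tss) <= promW)) return("Promoter")
  es <- GenomicRanges::start(model$exons)
  ee <- GenomicRanges::end(model$exons)
  if (any(posn >= es & posn <= ee)) return("Exon")
  if (any(posn >= gs & posn <= ge)) return("Intron")
  dsLo <- ifelse(strand != "-", ge + 1L, gs - downW)
  dsHi <- ifelse(strand != "-", ge + downW, gs - 1L)
  if (any(posn >= dsLo & posn <= dsHi)) return("Downstream")
  "Distal Intergenic"
}

# Coverage-weighted bin means by explicit per-bin loops.
bruteBinMeans <- function(pos, coverage, percent, binWidth) {
  bin <- ((pos - 1L) %/% binWidth) * binWidth
  sapply(sort(unique(bin)), function(b) {
    i <- bin == b
    sum(coverage[i] * percent[i]) / sum(coverage[i])
  })
}
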