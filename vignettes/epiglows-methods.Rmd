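---
title: "Methods: evaluating genotypes and 5mC methylation from low-pass nanopore sequencing"
author: "epiglows package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating genotypes and 5mC methylation from low-pass nanopore sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiglows)
```

## The problem

Low-pass sequencing (LPS) — whole-genome sequencing at well below 5×
depth — has become an attractive alternative to SNP arrays in livestock
genomic evaluation: a single nanopore run yields reads that can be used
simultaneously for genotyping (through imputed allele dosages) and for
5mC methylation calling, an "epi-genotyping by LPS" design. The question
the `epiglows` package addresses is *how well* that works: how accurate
are the basecalls, how do depth and error rate propagate into allele
dosages, how close are direct genomic values (DGVs) computed from those
dosages to DGVs computed from array genotypes, and how much 5mC signal
survives sensible coverage filters.

Because real low-pass cattle runs are large and not redistributable, the
package pairs every analysis stage with a synthetic-data generator that
emulates the statistical structure the stage assumes, with complete
known truth. Every claim the test suite makes is therefore a claim about
the method under a stated generative model, not about any particular
sequencing run.

## Per-read basecalling accuracy

For a mapped read, the SAM `NM` tag counts mismatches plus inserted plus
deleted bases. The single-nucleotide mismatch load of the read (the
*total mismatch score*, TMS) is therefore

$$\mathrm{TMS} = \mathrm{NM} - \mathrm{ins} - \mathrm{del},$$

with the CIGAR `I`/`D` operation totals supplying the indel lengths, and
the per-read accuracy is

$$\mathrm{accuracy} = 1 - \mathrm{TMS}/\ell,$$

with $\ell$ the read length. Two conventions exist for $\ell$; the
package uses the full query length (soft clips included) because TMS is
bounded by query bases, and exposes the aligned-length alternative by
simply passing a different length vector to `readAccuracy()`. TMS is
clamped at zero: a few aligners emit `NM` variants that can fall below
the CIGAR indel total, and a negative TMS indicates tag dialect, not
negative error. Reads of length ≤ 150 bp or mean quality < 10 are
discarded before scoring, and only primary alignments are counted.

The distribution of accuracies over reads is summarized by its median
and its mode; the mode is taken as the midpoint of the fullest histogram
bin (width 0.001 on the accuracy scale, ties resolved toward higher
accuracy) rather than by kernel density estimation, because a fixed-bin
mode is reproducible and directly testable against a brute-force argmax.

## Variant filtering rules

Calls from a low-pass run carry little per-site evidence, so two rules
are applied after calling:

* **Depth rescue.** Variants with depth ≤ 2 are discarded *unless* the
  variant — site and alternate allele, not position alone — is present
  in the reference panel, in which case panel support rescues it.
* **Zygosity from allele fraction.** A site is called heterozygous when
  the within-sample alt-read fraction lies strictly between 0 and 0.90;
  a fraction of 0 is homozygous reference, ≥ 0.90 homozygous alternate.
  The fraction is per-sample, not a population frequency.

Both boundaries are implemented exactly as worded (0 exclusive, 0.90
exclusive for the heterozygote band) and the boundary behaviour is
pinned by tests. Multi-allelic records are split into per-alt records
before filtering; coordinates are 1-based VCF coordinates throughout.

## Allele dosages without a reference-panel HMM

The real evaluation pipeline imputes low-pass calls against a large
haplotype panel. That step is deliberately not re-implemented: the
package replaces it with a per-site posterior under a Hardy–Weinberg
prior,

$$P(g \mid r, a) \propto \pi_g \binom{r+a}{a} p_g^{a} (1-p_g)^{r},
\qquad \pi = \{(1-p)^2,\, 2p(1-p),\, p^2\},
\qquad p_g = \{\epsilon,\, \tfrac12,\, 1-\epsilon\},$$

where $r, a$ are reference and alternate read counts, $p$ the population
alternate-allele frequency taken from the panel (never re-estimated from
the low-pass sample itself), and $\epsilon$ the per-read allele error.
The dosage allele (DA) is the posterior mean, a value in $[0, 2]$; a
site with no reads returns the prior mean $2p$, so marker vectors stay
complete for downstream scoring. Heterozygous genotypes are called for
$0.8 \le DA \le 1.2$ (inclusive), smaller dosages 0, larger 2.

This is the package's central, intentional departure from the pipeline
it evaluates. The per-site posterior reproduces the qualitative
behaviour that matters downstream — depth-dependent dosage uncertainty,
the heterozygote-vs-homozygote concordance asymmetry, monotone
improvement with depth — while remaining fully auditable against
brute-force enumeration. What it cannot reproduce is the *level* of
accuracy that linkage-disequilibrium-aware imputation achieves: the
posterior mean is the minimum-mean-squared-error estimator given only
the site's own reads, so its concordance and DGV closeness form a floor
(the no-LD baseline), not an estimate of what panel imputation would
give. Concretely, at 8× coverage with $\epsilon = 0.01$ and allele
frequencies uniform on (0.05, 0.5), the expected posterior variance
caps the dosage-vs-truth DGV $R^2$ at about 0.93; the test suite's
parameter-recovery check measures exactly that value, and its stated
0.95 bound documents the remaining gap attributable to linkage
information. At titration depths of 0.5–2× the gap is much larger,
which is why the package's depth-titration checks assert the direction
and ordering of the curves, not published magnitudes.

## Direct genomic values and closeness

For individual $i$ and trait $t$,

$$\mathrm{DGV}_{it} = \mu_t + \sum_{j=1}^{p} x_j \beta_{jt},$$

where $x_j$ is an array genotype or a dosage allele and $\beta_{jt}$ the
allele-substitution effect. Effects are fixed knowns (in practice they
come from an official genomic evaluation; here from the simulator); no
shrinkage or re-estimation is applied. Markers are matched by
(chromosome, position, alt allele); a marker whose ref/alt orientation
is swapped relative to the effects table is detected and its dosages
mirrored to $2 - x$ with a logged count. A marker present in the
effects but absent from the input is an error, never a silent zero.

Closeness between array-based and LPS-based DGVs is summarized by the
OLS regression of the array DGVs (the benchmark, as response) on the
LPS DGVs: $R^2$, intercept and slope, plus Pearson and Spearman
(average-rank) correlations. A positive intercept with slope below 1 is
the signature of dosage shrinkage toward the prior at low depth: LPS
underestimates high DGVs, and the bias grows as depth falls.

## Depth titration

To isolate the effect of depth, reads are subsampled uniformly without
replacement to target depths (default 0.5×, 1×, 1.5×, 2×): the retained
count is `round(target/source × n_reads)`, applied per individual, so
per-site kept counts follow a multivariate hypergeometric law — exactly
what thinning an alignment does to its pileup. The subsampling unit is
the read, not the site. Each (depth, replicate) cell re-runs dosage →
DGV → closeness and genotype concordance; the package defaults to 20
replicates for property checks (a single draw reproduces the original
single-pass protocol), reporting means and $n-1$ standard deviations.

## 5mC methylation analysis

bedMethyl records (BED9+2: coverage and percent-modified columns,
0-based half-open coordinates, converted to 1-based internally) are:

* **coverage-filtered** at ≥ 4×, ≥ 7× or ≥ 10× (inclusive; the site
  sets nest);
* **binned** into 500-bp windows with coverage-weighted mean percent
  methylation; agreement between two filter settings is the Pearson
  correlation over shared bins (≥ 3 required);
* **annotated** by genomic feature with priority Promoter (within
  ± 3,000 bp of any TSS) → Exon → Intron → Downstream (≤ 3,000 bp past
  the strand-appropriate gene end) → Distal Intergenic. The priority
  order is a choice: peak annotators resolve overlaps by precedence, and
  promoter-first matches the analytical focus on promoter methylation.
  UTRs are collapsed into Exon. The downstream window is set symmetric
  with the promoter window; both are parameters.
* **profiled** by strand-aware signed distance to the nearest TSS
  (negative = upstream), binned at 50 bp within ± 3,000 bp and
  normalized to sum to 1.

A "methylated site" for breakdowns and profiles is a site passing the
coverage filter with percent-modified > 0; the percent threshold is a
parameter because conventions differ.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults state the
study conditions the checks run under:

* **Panel** (`simulatePanel`): allele frequencies uniform on
  (0.05, 0.5) — the ascertained spectrum typical of a genotyping array —
  genotypes Binomial(2, p) per site (HWE, no LD), positions uniform and
  unique on one chromosome, per-trait effects $\beta \sim N(0, 1)$ for
  three traits (the effect distribution of a real evaluation is not
  public; a zero-mean normal is the standard stand-in). No LD is
  simulated because no stage of the package exploits LD.
* **Pileups** (`simulatePileups`): coverage Poisson($\lambda$) per
  site × individual; each read reports the true allele with probability
  $1-\epsilon$, one symmetric error parameter for both alleles — the
  simplest model that produces the het/hom concordance asymmetry.
* **Reads** (`simulateSamReads`): truncated-normal lengths,
  substitutions at a per-base rate, single-base indels split evenly
  between insertion and deletion; the emitted `NM` equals the injected
  edits by construction and per-read truth is retained for assertions.
* **Methylation** (`simulateMethylation`): per-CpG level from a
  hypo/hyper Beta mixture (weights 0.3/0.7, shapes (1.5, 8) and
  (8, 1.5) — the bimodal, mostly-methylated pattern of vertebrate
  genomes), coverage Poisson, modified count Binomial(coverage, level).

One global seed expands into fixed per-stage substreams
(`stageSeed()`), so identical configurations give byte-identical
fixture files and any stage can be regenerated alone.

What the generator does **not** emulate: linkage disequilibrium,
nanopore-specific error profiles (homopolymer errors, strand bias),
pedigree structure, CpG-island spatial autocorrelation. Passing tests
therefore validate the arithmetic and the direction of depth/error
effects, not performance on real nanopore data.

## Problem sizes and numerical choices

The routine checks use deliberately modest sizes chosen to exercise the
statistics well past sampling noise: 10,000 site-by-individual draws for
moment checks (3-standard-error bands), 200 individuals × 2,000 markers
× 10 seeds for parameter recovery, 100 × 1,000 × 20 replicates for the
depth ladder, 10,000 CpG sites at $\lambda = 12$ for the filter
agreement. Posterior computations are exact enumerations over the three
genotypes (no sampling); ties in the accuracy-mode histogram break
toward higher accuracy; degenerate inputs (zero-variance closeness
vectors, empty TSS windows, fewer than three shared bins) return `NA`
with a warning rather than failing.

## A small worked example

```{r, eval = FALSE}
panel <- simulatePanel(nIndividuals = 50, nSnps = 500, seed = 1)
pileups <- simulatePileups(panel, meanDepth = 2, errorRate = 0.01, seed = 2)
dosages <- dosageMatrix(pileups, alleleFreqs(panel), errorRate = 0.01)
eff <- effectsTable(panel)
closeness(computeDgv(genotypes(panel), eff, "MY"),
          computeDgv(t(dosages), eff, "MY"))
```

## Known limitations

* Dosage accuracy is a no-LD floor; absolute concordance and $R^2$
  published for panel-imputed low-pass data will exceed what this
  package's stand-in produces at the same depth.
* The uniform symmetric error $\epsilon$ ignores context-dependent
  nanopore errors; accuracy summaries on real data should be computed
  from real alignments (the readers accept any SAM/BAM).
* Feature annotation assumes one transcript per gene (TSS at the gene
  span end); alternative promoters are not modelled.
* The per-kit summary machinery reports sample ($n-1$) standard
  deviations and offers both round-half-away and truncate display modes,
  because published tables mix the two conventions.
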