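Package: epiglows
Title: Epi-Genotyping by Low-Pass Nanopore Sequencing: Dosages, Genomic
    Values and 5mC Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation toolkit for epi-genotype-by-low-pass-sequencing
    (EpiGLowS) experiments. Scores per-read basecalling accuracy from
    SAM edit distances and CIGAR indel lengths, applies depth-rescue and
    allele-fraction zygosity filters to low-pass variant calls, derives
    posterior allele dosages from read counts under a Hardy-Weinberg
    prior, computes direct genomic values (DGVs) from marker effects and
    their closeness to array-based DGVs, titrates performance against
    sequencing depth by read subsampling, and analyses 5mC bedMethyl
    calls under coverage filters with promoter/TSS annotation. Ships a
    synthetic-data generator with known truth so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    vcfR,
    Rsamtools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
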