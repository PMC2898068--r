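Package: snvconcord
Title: Concordance of Genome- and Transcriptome-Derived SNV Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks single nucleotide variant (SNV) calls made from RNA-Seq
    (cDNA) against calls made from whole-genome sequencing (gDNA) of the same
    individual. Applies the quality-control screens used for pileup-style call
    sets (minimum SNP quality, minimum alternate-allele support, maximum site
    depth, end-of-read artifact fraction), restricts calls to annotated exons,
    classifies the two call sets into true positives, false positives and false
    negatives by position or by exact genotype, and computes sensitivity
    (TP/(TP+FN)) and specificity (TP/(TP+FP)) overall and within strata:
    log-spaced transcript-expression bins, read-depth windows, paralog status,
    exon subsets, known-site (dbSNP-like) membership and cumulative sequencing
    lanes. A ground-truthed synthetic-data generator emulates heavy-tailed
    transcript expression, expression-proportional Poisson read depth, binomial
    allele sampling with allelic imbalance, and paralog-misalignment,
    end-of-read and base-error false-positive processes, so the whole pipeline
    is testable without raw reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
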