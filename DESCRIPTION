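Package: evoselect
Title: Analysis of Multigenerational Insecticide-Selection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evolve-and-resequence studies of insecticide resistance
    in mosquito lines selected over many generations. Provides bioassay and
    target-site genotype monitoring statistics, a differential-transcription
    stage (median-of-ratios normalization, per-gene ANOVA with Tukey HSD
    contrasts and Benjamini-Hochberg correction), transcript-polymorphism
    selection scans combining a replicate allele-frequency shift test with a
    Bayesian F(ST) outlier model fitted by reversible-jump MCMC, gene-level
    genome scans, and a Wright-Fisher viability-selection simulator that
    generates complete synthetic experiments (counts, VCF, GFF3, genotype and
    bioassay tables) with a ground-truth ledger for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    ggplot2,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
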