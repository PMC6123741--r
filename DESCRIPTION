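Package: cicadapop
Title: Demographic Inference and Parallel-Divergence Scans for Periodical
    Cicada Broods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genomic analysis of parallel 13-/17-year life-cycle
    divergence in Magicicada periodical cicadas. Provides a structured
    coalescent simulator for divergence-with-migration histories of four
    brood demes, folded joint site-frequency spectra with Poisson bootstrap
    resampling, composite-likelihood fitting and AIC-based comparison of
    nine demographic models, Weir-Cockerham F_st at SNP and locus level with
    simulation-calibrated outlier thresholds and a shared-outlier
    permutation test, frequency-based ABBA-BABA D-statistics with locus
    bootstrap, repeated random haplotype sampling (RRHS) estimates of
    nucleotide diversity, d_xy and Tajima's D from unphased genotypes, and
    non-linear fitting of a time-dependent substitution-rate curve.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    ape,
    vcfR,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
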