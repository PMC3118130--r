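Package: snpanel
Title: Informative SNP Marker Selection and Likelihood-Based Population Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building reduced panels of ancestry-informative SNP
    markers from population allele frequencies and for verifying the origin of
    individuals by likelihood-based assignment. Implements four per-locus
    informativeness measures (delta, Wright's Fst, Weir & Cockerham's Fst and a
    PCA squared-loading score), Paetkau-style multilocus genotype likelihoods
    with log-likelihood-ratio stringency thresholds, cumulative-panel
    assignment curves with asymptotic-regression estimation of the minimum
    panel size, random-panel controls, training/holdout cross-validation, and a
    Balding-Nichols multi-breed simulator for end-to-end testing without
    genotype downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
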