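Package: coxmdr
Title: Gene-Gene Interaction Detection for Survival Phenotypes via
    Martingale-Residual Multifactor Dimensionality Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects SNP-SNP interactions associated with censored survival
    times using Cox-MDR, a multifactor dimensionality reduction (MDR) method
    that classifies multi-locus genotype cells as high or low risk by the sum
    of martingale residuals from a covariate-only Cox proportional hazards
    model. Includes the Surv-MDR comparator (per-cell log-rank
    classification), a univariate Cox regression screen with
    Benjamini-Hochberg false discovery rate control, cross-validated
    combination search with permutation p-values, and a simulation engine
    generating pure-epistasis penetrance models at target heritability and
    minor allele frequency with Cox-Weibull survival cohorts for power and
    type-I-error studies. Results are returned as tibbles with broom-style
    tidiers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
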