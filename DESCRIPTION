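Package: ratiomr
Title: Two-Sample Mendelian Randomization with Ratio-Phenotype Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A summary-statistics Mendelian randomization (MR) toolkit built
    around enzyme-activity exposures proxied by product-to-substrate
    biomarker ratios. Derives GWAS summary statistics for a ratio of two
    phenotypes by the delta method (inferred ratio GWAS), harmonizes
    exposure and outcome summary statistics to a shared effect allele,
    selects independent instruments by P-value threshold and greedy LD
    clumping, and estimates causal effects with the Wald ratio and
    inverse-variance weighted estimators. Includes fixed-effects
    meta-analysis across studies with allowance for shared controls,
    DerSimonian-Laird random-effects pooling across outcomes,
    mixed-effects meta-regression on outcome-level covariates, Bayesian
    colocalisation via per-SNP approximate Bayes factors,
    product-of-coefficients effect decomposition, phenome-wide MR scans
    with Bonferroni control, binary-outcome MR power, and a fully seeded
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
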