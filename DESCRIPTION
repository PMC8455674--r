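Package: mrkit
Title: Two-Sample Mendelian Randomization with GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bi-directional two-sample Mendelian randomization from GWAS
    summary statistics: instrument selection (genome-wide significance,
    greedy LD clumping, proxy substitution), allele harmonization with
    frequency-based resolution of palindromic variants, causal estimation
    by inverse-variance weighting with multiplicative random effects,
    weighted median and MR-Egger regression, MR-PRESSO outlier detection
    and correction, instrument-strength (F-statistic) and power
    diagnostics, Bonferroni multiple-testing control, and a fully seeded
    synthetic summary-statistic generator with known causal truth for
    estimator validation.
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
    jsonlite,
    magrittr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
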