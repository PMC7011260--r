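Package: metacred
Title: Credibility Re-Analysis of Genetic Association Meta-Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for field-synopsis re-analysis of genetic association
    meta-analyses. Reconstructs log odds-ratio standard errors from published
    confidence intervals, computes false-positive report probability (FPRP)
    and Bayesian false discovery probability (BFDP) over grids of prior
    probabilities and detection odds ratios using numerically stable log-space
    routines, grades cumulative evidence with the Venice criteria, and
    combines noteworthy variants into per-SNP and joint population
    attributable risk. Ships transcriptions of a published migraine synopsis
    as fixtures and a seeded simulator of case-control meta-analysis
    catalogues for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
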