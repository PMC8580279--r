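Package: mrcovadj
Title: Bias in Two-Sample Mendelian Randomization with Covariable-Adjusted Summary Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework and estimation pipeline for quantifying bias
    in two-sample Mendelian randomization (MR) when genome-wide association
    study (GWAS) summary associations have been adjusted for a heritable
    covariable. Generates individual-level cohorts under configurable causal
    structures linking genetic variants, an exposure, a covariable, an
    intermediate trait and an outcome, with optional unmeasured confounding;
    computes per-variant summary associations with or without covariable
    adjustment; selects instruments by F statistic or p-value; and estimates
    causal effects by multiplicative random-effects inverse-variance
    weighting, including harmonization of user-supplied summary statistics.
    A Monte-Carlo driver aggregates bias, coverage and instrument-count
    summaries across scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
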