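Package: tsmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrument selection, allele harmonization and causal-effect
    estimation for two-sample Mendelian randomization from GWAS summary
    statistics. Implements the inverse-variance-weighted estimator, MR-Egger
    regression with its pleiotropy intercept, weighted-median and mode-based
    robust estimators, profile maximum likelihood, the robust adjusted
    profile score, Cochran's Q heterogeneity tests and leave-one-out
    sensitivity analysis, together with a summary-statistics simulator with
    known causal truth for calibration and recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
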