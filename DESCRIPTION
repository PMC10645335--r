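Package: peaquant
Title: Quantitative Proximity Extension Assay Processing and Case-Cohort
    Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes multiplex Proximity Extension Assay (PEA) qPCR plates
    from raw cycle-threshold values to absolute protein concentrations:
    extension-control and calibrator normalization to NPX, four-parameter
    logistic standard curves with limits of detection and quantification,
    value reassignment against clinical reference assays, and censored
    lognormal imputation.  Ships the analytical-validation metric suite
    (linearity of dilution, QC accuracy and precision, dynamic-range
    coverage, method comparison) and a case-cohort prognostic-modelling
    layer (weighted Cox partial likelihood with robust sandwich errors,
    restricted cubic splines, quartile hazard ratios, Harrell's C, fraction
    of new information, bootstrap optimism correction).  Includes synthetic
    plate and cohort generators so the full pipeline runs end to end
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    fitdistrplus,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
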