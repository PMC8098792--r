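Package: rerin
Title: Multi-Way Additive Interaction Among Binary Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures of additive interaction among two or more binary
    exposures on a relative-risk scale: the relative excess risk due to
    interaction (RERI) for two factors, its total and top-order
    generalisations for n factors, conditional lower-order RERIs within
    strata of the remaining factors, the exact decomposition of the total
    RERI into interaction components, and the multiplicative interaction
    index.  Estimation pathways from saturated logistic or Cox regression
    models (with delta-method standard errors and Wald confidence
    intervals), from exported coefficient vectors with a covariance
    matrix, and from 2^n contingency tables of cases and denominators.
    Includes detection and reorientation of protective factors, and a
    synthetic-cohort simulation harness for bias and confidence-interval
    coverage evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
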