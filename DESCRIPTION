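Package: genqsar
Title: Genetic QSAR Model Building and Validation for Antioxidant Phenols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric toolkit for quantitative structure-activity
    relationship (QSAR) modelling of small molecules from tabulated
    molecular descriptors: rational training/test division by k-means
    clustering in standardized descriptor space, stepwise multiple linear
    regression with F-to-enter/F-to-remove control, genetic function
    approximation (GFA) over linear, truncated-power-spline and quadratic
    basis terms scored by Friedman's lack-of-fit, genetic partial least
    squares (G/PLS) with NIPALS, and the full internal/external validation
    suite: leave-one-out Q2 and PRESS, predictive R2, the rm2 metrics,
    Y-randomization statistics (Rp2 and corrected cRp2), and a DModX
    applicability domain.  Ships the published activity and prediction
    tables for a series of 33 NO-donor phenolic antioxidants as packaged
    fixtures, plus a synthetic-data generator with known sparse ground
    truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
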