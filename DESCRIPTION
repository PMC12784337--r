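Package: mixedrrr
Title: Reduced-Rank Regression for Mixed Numeric, Binary and Ordinal Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood reduced-rank regression for multivariate
    outcomes that mix numeric, binary and ordinal response variables, with
    optimal scaling (quantification) of numeric, binary, nominal and ordinal
    predictors.  Estimation uses a majorization-minimization algorithm with
    quadratic upper bounds for the logistic losses, a closed-form EM
    expectation for the ordinal latent variable, weighted monotone regression
    for ordinal quantifications and an orthogonal Procrustes update for the
    loadings.  Includes parameter counting, AIC/BIC/adjusted McFadden model
    selection, repeated V-fold cross-validation, a balanced pairs bootstrap
    with confidence-ellipse origin tests, and synthetic-data generators for
    the accompanying simulation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
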