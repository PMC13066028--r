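Package: mvdreg
Title: Multivariate Gaussian Distributional Regression for Child Malnutrition Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Joint distributional regression for the four child-malnutrition
    indicators hemoglobin (Hb), height-for-age (HAZ), weight-for-age (WAZ) and
    weight-for-height (WHZ) as a four-dimensional Gaussian response whose mean
    vector and covariance matrix both depend on covariates.  The covariance is
    parameterised through the modified Cholesky decomposition, giving 14
    unconstrained distributional parameters (4 means, 4 log innovation scales,
    6 regression coefficients of the Cholesky factor), each modelled by an
    additive predictor with penalised splines and a spatial tensor-product
    smooth.  The package provides spatially representative train/test splits
    via Delaunay triangulation, componentwise gradient boosting for term
    selection, Bayesian estimation by Markov chain Monte Carlo with
    iteratively-weighted-least-squares proposals, derivation of gridded
    prevalence and pairwise-correlation surfaces with pixel masking, age
    profiles at buffered locations, calibration diagnostics, and a synthetic
    cluster-survey generator for testing every stage without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    splines,
    deldir,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
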