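Package: vaxsae
Title: Discrete and Continuous Spatial Models for District-Level
    Vaccination Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-area estimation of vaccination coverage from
    cluster-survey data. Implements design-based direct (Horvitz-Thompson)
    estimators with linearized variances, three discrete-area Bayesian
    smoothing models (unweighted binomial, logit-normal, and effective
    sample size, all with a Leroux conditional autoregressive prior), and
    two continuous geostatistical binomial models with Matern (nu = 1)
    Gaussian-process random effects and penalized-complexity priors.
    Includes population-weighted aggregation of gridded posterior surfaces
    to districts, exceedance-probability summaries, leave-one-district-out
    cross-validation with RBias, RMSE, MAE and CRPS, and a synthetic-country
    generator emulating stratified two-stage cluster surveys for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    deldir,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
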