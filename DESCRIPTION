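Package: spatord
Title: Spatial Ordinal Regression for Cluster-Sampled Household Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical cumulative-logit ordinal regression for
    georeferenced, cluster-sampled household survey data, as used for
    small-area mapping of water, sanitation and hygiene (WASH) service
    levels. The latent predictor combines fixed covariate effects, an
    i.i.d. Gaussian cluster random effect and a Matern Gaussian random
    field represented through the stochastic partial differential
    equation (SPDE) finite-element approximation on a triangulated mesh.
    Parameters are estimated by maximising a Laplace-approximated
    marginal likelihood with sparse inner Newton optimisation of the
    random effects. Includes a synthetic survey generator emulating
    DHS/MICS-style cluster sampling, gridded probability and
    delta-method standard-error surfaces written as GeoTIFF rasters,
    and a diagnostic suite (Dunn-Smyth randomised quantile residuals,
    calibration curves, posterior predictive checks, per-class
    classification metrics and exact Shapley attributions of the linear
    predictor).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
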