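Package: hmb3
Title: Three-Phase Hierarchical Model-Based and Hybrid Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predictors, analytic variances, variance estimators and
    mean-squared-error formulas for a population mean predicted through three
    hierarchically nested regression models, as used in forest biomass
    (aboveground biomass density) assessment combining field plots, sampled
    LiDAR and wall-to-wall optical satellite data. Supports both three-phase
    hierarchical model-based inference (final-phase covariates available
    wall-to-wall) and three-phase hierarchical hybrid inference (final-phase
    covariates available for a probability sample, combined through a
    Horvitz-Thompson estimator under simple random sampling without
    replacement). Includes a multivariate-normal superpopulation simulator
    that derives the true model-chain parameters from chained correlations,
    and a Monte-Carlo validation harness for the variance formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
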