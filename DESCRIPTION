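Package: xylemclim
Title: Height and Climate Drivers of Conifer Xylem Anatomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantitative wood anatomy at climatic treelines:
    reconstructs annual tree height and diameter from ring-width series,
    classifies tracheids into earlywood and latewood by Mork's index,
    builds annual chronologies of lumen area, conduit reinforcement,
    anatomical density and cell-wall thickness, aggregates monthly climate
    into seasonal predictors, and fits restricted-maximum-likelihood mixed
    models with per-tree random slopes, first-order autocorrelated errors
    and per-tree variance weights to separate direct climatic effects from
    indirect, height-mediated ones. Includes Weibull height-diameter
    allometries, regional-curve ring-width age trends, Tukey-adjusted site
    contrasts, counterfactual prediction experiments, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    optparse
Config/testthat/edition: 3
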