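Package: invadescape
Title: Landscape-Trait Interactions in Simulated Plant Invasions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates stochastic spread of a perennial plant invader across
    categorical habitat rasters, generates synthetic landscapes spanning a
    fragmentation gradient, computes a 50-metric registry of landscape
    composition and spatial-structure characteristics, and quantifies how
    landscape effects on invasion outcomes interact with invader traits via a
    two-stage Bayesian analysis: a Laplace-prior (lasso) regression of each
    invasion response on standardized landscape metrics with the shrinkage
    rate selected by held-out log predictive density, followed by a Bayesian
    linear model regressing the resulting coefficients on dispersal, growth,
    establishment, and corridor-usage traits.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
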