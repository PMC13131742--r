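Package: nlmrhet
Title: Nonlinear Mendelian Randomization Under Instrument-Exposure Effect
    Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for studying how heterogeneity
    in genetic instrument-exposure effects biases nonlinear Mendelian
    randomization. Provides a generative simulator for polygenic exposures
    with homogeneous, gene-by-confounder and gene-by-environment interaction
    effects; polygenic-score instrument construction with genome-wide
    significance selection; a Breusch-Pagan heterogeneity screen; polynomial
    two-stage least squares (with AIC degree selection), control-function and
    PolyMR-style estimators, sieve nonparametric instrumental variables with
    uniform confidence bands, and residual- and doubly-ranked stratification
    with quadratic, Cochran's Q and Cauchy-combination tests; plus an
    evaluation harness computing bias, mean squared error, coverage, type I
    error and power over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lmtest,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
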