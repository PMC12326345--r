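Package: compactmix
Title: Interaction-Based Prediction of Tablet Tensile Strength for Powder Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modeling the compactibility of pharmaceutical powders
    and predicting the tensile strength of compacted multicomponent mixtures.
    Converts raw tablet measurements (weight, dimensions, failure force) into
    porosity and diametral tensile strength, fits Ryshkewitch-Duckworth
    compactibility profiles by nonlinear least squares, and predicts mixture
    strength with interaction-cluster models of arbitrary order in which
    cluster abundances follow a multinomial distribution over component volume
    fractions and cluster strengths are geometric means of component
    strengths. Classical comparators (linear mixing rule, power law, and
    Ryshkewitch-Duckworth parameter-combination rules) and RMSE-based model
    comparison are included, together with a seeded synthetic-data generator,
    a formulation design-space explorer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
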