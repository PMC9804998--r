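Package: mesolim
Title: Mesophyll Conductance Standardisation, Quality Control and
    Limitation Analysis for Leaf Gas-Exchange Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analysis of leaf mesophyll conductance (gm)
    measurements compiled from heterogeneous gas-exchange studies.
    Standardises gm to common units at 100 kPa and to a reference leaf
    temperature of 25 degrees C, applies measurement-condition filters and
    a two-step plant-functional-type specific outlier screen, reconciles
    multi-method measurements, quantifies the relative photosynthetic
    limitation imposed by gm with an exponential limitation curve, and
    relates gm to leaf anatomical and biochemical traits with robust
    regressions and a gamma log-link generalised linear model. Includes a
    Rubisco-limited leaf gas-exchange simulator for generating synthetic
    cohorts with known structure, so every pipeline stage can be tested
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    MASS,
    minpack.lm,
    stats,
    jsonlite,
    yaml,
    withr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
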