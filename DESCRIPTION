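Package: clocklineage
Title: Stochastic Lineage Simulations of Coupled Circadian Clock and
    Cell Cycle Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates single-cell lineages in which an intracellular
    circadian clock gene network (PER-CRY negative feedback with an
    optional REV-ERBalpha/BMAL1 secondary loop) is coupled to a
    WEE1-gated MPF cell cycle oscillator.  Model equations are
    integrated as chemical Langevin stochastic differential equations
    with the Euler-Maruyama scheme; dividing cells build binary lineage
    trees from which intermitotic-time correlation structures (sister,
    cousin, mother-daughter and deeper vertical-generation
    correlations, and the cousin-mother inequality) are extracted.
    Includes entrainment spectroscopy of the two oscillators, modelling
    of the clock inhibitor KL001 as a stabilisation of the PER-CRY
    complex, population growth-rate fitting, and ergodic age-structure
    predictions for cell cycle phase proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
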