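Package: eprsim
Title: Particle Simulation of EPR-Mediated Fluorophore Biodistribution and
    Tumor-to-Background Ratio Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, seed-deterministic 3D particle model of contrast-agent
    biodistribution for fluorescence-guided surgery. Fluorophore particles are
    released in batches into a reflective chamber (the imaging field of view),
    random-walk on rectilinear trajectories, are funnelled into a spherical
    tumor region of interest by an optional enhanced permeability and
    retention (EPR) zone with viscosity-reduced speeds and a stochastic escape
    rule, and are removed by independently scheduled background and tumor
    clearance events. The package records percentage fluorophore distribution
    over time, summarizes contrast phenomenology (peak uptake, crossover,
    contrast window, detectability onset in off-to-on responsive mode), ships
    the six documented simulation presets, and implements total-radiant-
    efficiency based tumor-to-background ratio (TBR) quantification for
    longitudinal imaging series, with a synthetic time-course generator for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
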