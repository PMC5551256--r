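Package: luccesv
Title: Land-Use Change Metrics, Markov-CA Simulation, and Ecosystem Service Valuation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing land-use and land-cover change (LULCC) from
    co-registered categorical rasters: class-by-class transition matrices with
    single and comprehensive land-use dynamic degrees, Cohen's kappa map
    agreement, Markov-chain estimation and projection of class areas, a
    cellular-automaton allocator that turns projected areas into simulated
    maps, equivalent-factor ecosystem service valuation (ESV) with zonal
    aggregation, and an elasticity-style sensitivity index of ESV to LULCC.
    Includes a seeded synthetic-landscape generator so the full pipeline is
    testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
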