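Package: fepnet
Title: Network Analysis of Alchemical Relative Binding Free Energy Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for turning pairwise alchemical free energy perturbation
    estimates into per-ligand relative binding free energies. Aggregates
    directional, repeated perturbation runs into a weighted perturbation
    network, combines all simple paths to a reference compound by
    inverse-error weighting with propagated uncertainties, collapses
    alternative binding modes by exponential (Boltzmann) averaging, applies
    charge-scaling polarisation corrections, and scores predictions against
    IC50-derived experimental values with bootstrap confidence intervals on
    Pearson R and the mean unsigned error. Includes convergence diagnostics
    for lambda-gradient timeseries (thermodynamic integration, stationarity
    testing, estimator consistency) and a synthetic-data generator that
    emulates the statistical structure of perturbation studies so the whole
    pipeline can be exercised without molecular dynamics simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
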