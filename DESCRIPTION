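Package: traploop
Title: Design and Simulation of Valve-Controlled Hydrodynamic Single-Cell Traps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and simulating microfluidic single-cell
    trapping devices that combine hydrodynamic trapping with multilayer
    membrane valves.  Implements the rectangular-duct resistance-network
    design model (hydraulic diameter, Shah-London fRe, per-region pressure
    drops, the Q2/Q1 < 1 trapping criterion), a depth-averaged
    Stokes-Brinkman flow solver with Lagrangian particle tracing for
    trap/bypass transmission probabilities under valve control, a trap-array
    fill/release simulator with valve scheduling, and a synthetic
    single-molecule localization (PALM) module with nearest-neighbour
    localization-precision and density-cluster estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    Matrix,
    jsonlite,
    readr,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
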