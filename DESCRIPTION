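Package: dynlane
Title: Multilane Exclusion-Process Simulation of Variable-Step Molecular Motors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Kinetic Monte Carlo simulation of a driven lattice gas of
    hard-core particles with internal ATP-binding states and variable step
    length (1-4 sites), on an open-ended cylinder of lanes with periodic
    transverse boundaries. The model mimics collective dynein motor traffic
    on a microtubule. Provides the stochastic sweep engine (injection,
    multi-step hopping with a no-overtaking sliding rule, lane changes,
    extraction), the closed-form mean-field current analysis with its
    maximal-current thresholds, observables (density profiles, bond
    currents, jump-length statistics, tagged-particle mean-square
    displacement, dwell-time distributions and their fits), and
    boundary-rate phase-diagram scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
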