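Package: pearlchain
Title: Compartmental Simulation of Action Potentials and After Potentials
    in Hippocampal Mossy Fiber Axons
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-compartment Hodgkin-Huxley cable model of a hippocampal
    mossy fiber approximated as a "pearl chain" of thin axonal cylinders and
    large en passant boutons. Provides an implicit (backward Euler or
    Crank-Nicolson) tridiagonal cable solver with per-compartment recording of
    membrane potential and every membrane current component including the
    capacitive current, declarative in-silico protocols (regional conductance
    knockouts, local K+ reversal overrides, resting-potential retuning,
    current-step families, membrane-capacitance sweeps), and a measurement
    layer (spatial and temporal exponential fits, baseline alignment, ionic
    versus capacitive decomposition of the axonal after potential).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
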