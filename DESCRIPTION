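Package: netkin
Title: Network Simulation Method for Chemical Reaction Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Solves systems of first-order mass-action kinetic equations by
    the Network Simulation Method: every species becomes a node of an
    equivalent electrical circuit (a unit capacitor carries the time
    derivative of the concentration, one voltage-controlled current source
    per rate term carries the coupling, and a high-value resistor guarantees
    continuity), which can be exported as a PSpice-dialect netlist or
    integrated natively with a variable-step trapezoidal/BDF2 scheme with
    SPICE-style relative-tolerance error control. Rate constants may be given
    directly or as free-energy barriers via the Eyring equation. Includes
    steady-state detection, steady-state-approximation (QSSA) solving and
    validation, phase-space extraction and largest-Lyapunov-exponent chaos
    diagnostics, built-in models (Diels-Alder cycloaddition, Chapman ozone
    cycle, Olsen peroxidase-oxidase oscillator, damped oscillator), a random
    scheme generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
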