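Package: fallfit
Title: Inverted-Pendulum Fall Simulator Dynamics, Fitting and Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dynamic model of a counterweighted inverted-pendulum fall
    simulator: a participant-carrying platform released from a lean angle,
    coupled through a four-pulley capstan-friction cable system to a
    counterweight that modulates the fall acceleration. Provides the
    equations of motion and their closed-form energy-balance solution,
    adaptive ODE simulation with angle-landmark event detection, zero-phase
    Butterworth processing of sampled angle and ground-reaction-force
    traces, constrained fitting of pendulum length and capstan friction by
    maximizing variance accounted for in angular velocity at the 70-degree
    readout, inverse counterweight design for a target impact speed, and a
    synthetic-cohort trial generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
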