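Package: homeostat
Title: Coherent-Feedback Homeostats: Simulation and Background-Compensation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates reaction-kinetic integral controllers (homeostats) in
    which a two-layer negative feedback holds both a controlled variable and
    its manipulated variable at set-points, and analyses their responses to
    step perturbations applied on top of constant backgrounds.  Implements
    five reference networks (oscillatory motif-2 and motif-8 schemes with
    coherent feedback, a first-order non-oscillatory variant, a dual
    inflow-controller scheme, and an incoherent-feedback oscillator), a
    stiff ODE simulation engine with piecewise-constant perturbation
    schedules, per-cycle frequency and response-amplitude statistics,
    background-compensation sweep experiments, and the Naka-Rushton
    intensity-response algebra used to analyse retinal light adaptation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
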