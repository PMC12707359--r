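Package: nanoswitchr
Title: Simulation and Quantification for Particle-Nanoswitch Biosensors
Version: 0.1.0
Authors@R:
    person("Nanoswitch", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Signal-processing and quantification pipeline for reversible
    sandwich-based particle-nanoswitch biosensors (biosensing by particle
    motion). Converts single-particle trajectories into windowed diffusion
    coefficients, bound/unbound state calls and unbound-to-bound (UTB)
    switching activity; normalizes activity against reference samples to
    cancel sensor drift; fits and inverts a four-parameter logistic
    dose-response; and computes precision and accuracy metrics (CV,
    precision-profile LoQ, blank-based LoD, MARD, imprecision distribution
    fits). Includes a synthetic-data generator that simulates the sensor's
    stochastic two-state sandwich kinetics, confined Brownian particle
    motion with localization noise, multiplicative sensor drift and
    Poisson event counting, so the whole pipeline is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
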