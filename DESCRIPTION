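Package: purkinjetimer
Title: Biophysical Model of Time-Interval Learning in a Purkinje-Cell Dendrite
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a coupled kinetic model of interval timing in a single
    Purkinje-cell dendritic microdomain during delay eyeblink conditioning. A
    calcium store (Somogyi-Stucki oscillator) acts as an intracellular clock,
    adenylyl cyclase detects the coincidence of the calcium signal with
    climbing-fiber-evoked stimulatory G protein, the cAMP-PKA pathway feeds
    back positively on calcium release, and a calcium-gated RGS protein
    provides the negative feedback whose activation time learns to anticipate
    the unconditioned stimulus. Provides a fixed-step backward-Euler
    integrator with a Runge-Kutta cross-check, a conditioning-protocol engine
    (single pairings, training series, inter-stimulus-interval sweeps),
    learning read-outs (anticipation latency, pairings-to-learn curves,
    calcium-release amplification), and constraint-guided parameter
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    lhs,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
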