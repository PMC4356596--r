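Package: mtorswitch
Title: Rule-Based Simulation of the AMPK-MTORC1-ULK1 Autophagy/Translation Switch
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A rule-based model of mutual inhibition between MTORC1 and the
    autophagy-initiating kinase ULK1, with reciprocal regulation by AMPK.
    Interaction rules written in a BNGL-style site-graph dialect are expanded
    into a concrete mass-action reaction network (species enumeration with
    canonical labeling), which is integrated as a stiff ODE system.  The
    package implements a numerical bifurcation protocol for this class of
    models (slow-drift parameter sweeps, hysteresis and limit-cycle detection,
    oscillation period and phase-duration measurement, two-parameter regime
    maps) and a one-at-a-time parameter robustness scan that classifies the
    canonical translation/oscillation/autophagy response pattern.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
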