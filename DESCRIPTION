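Package: kuranet
Title: Whole-Brain Kuramoto Simulation with a Strength-Dependent
    Timescale Hierarchy and Virtual Stimulation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates resting-state whole-brain dynamics as a network of
    Kuramoto phase oscillators coupled through a structural connectome, with
    each region's natural frequency assigned from its anatomical node
    strength so that high-strength hubs fluctuate slowly and low-strength
    sensory regions fluctuate fast. Provides connectome reading, validation
    and transformation (normalization, density sparsification, distance
    correction), a synthetic connectome and BOLD-signal generator with
    designated hub and sensory nodes, functional-connectivity and
    amplitude-of-low-frequency-fluctuation (ALFF) metrics, exact and
    approximate paired signed-rank statistics with Bonferroni correction,
    and a virtual-inhibition experiment framework: coupling calibration,
    paired pre/post trials in which a target region's natural frequency is
    slowed, frequency-reduction sweeps, control-site experiments and
    per-region statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
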