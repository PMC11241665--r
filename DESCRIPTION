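Package: gabapool
Title: Analysis of GABAergic Synaptic Transmission and Vesicle-Pool Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing inhibitory postsynaptic currents recorded in
    voltage clamp: detection and kinetic characterization of miniature IPSCs
    (biexponential decay fits, inter-event-interval distributions), evoked-IPSC
    charge, failure-rate and paired-pulse analysis with overlap correction, and
    estimation of readily releasable pool (RRP) size and replenishment rate from
    high-frequency stimulus trains by back-extrapolation of biphasic cumulative
    charge. Includes a stochastic two-pool quantal release simulator (binomial
    release, depletion, replenishment, facilitation) that generates synthetic
    recordings with known ground truth, so every analysis stage can be validated
    by parameter recovery, and a group-comparison workflow with a normality gate
    choosing between Student's t and Mann-Whitney tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm,
    nortest
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
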