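Package: epinetsim
Title: Timescale-Separated Epileptor Networks for Focal Seizure Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of whole-brain epileptic networks built
    from Epileptor neural-mass oscillators coupled through the slow
    permittivity variable. Provides the single-oscillator model with regime
    classification and epileptogenicity-threshold localization, generators
    for fully connected base networks with prominently embedded focal
    subnetworks (regular, small-world, random, scale-free) and
    truncated-normal excitability profiles, a fixed-step RK4 integrator for
    the coupled system, seizure event detection with recruitment and period
    statistics, and correlation-based functional networks with proportional
    thresholding and focal-degree summaries. Experiment drivers reproduce
    the threshold scan, recruitment, period-sweep and
    excitability-heterogeneity analyses end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
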