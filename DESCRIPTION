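Package: longsnn
Title: Spiking Neural Network Modelling of Longitudinal Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models longitudinal social and cognitive assessment data with a
    three-dimensional spiking neural network reservoir.  Sparse five-visit
    measurements are linearly interpolated to dense time series, encoded into
    signed spike trains by a threshold rule on consecutive changes, and fed
    into a small-world leaky integrate-and-fire reservoir trained with
    spike-timing-dependent plasticity.  A dynamic evolving spiking neural
    network (deSNN) rank-order readout classifies subjects; connection-weight
    summaries and feature interaction networks quantify how variables
    exchange information during learning.  Includes a seeded synthetic cohort
    generator emulating a three-group (healthy control / remitter /
    maintained) ultra-high-risk study design, and a repeated two-fold
    cross-validation harness reporting balanced accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
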