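Package: delaygene
Title: Delayed Stochastic Simulation and Markov Chain Inference for
    Single-Gene Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact stochastic simulation of single-gene transcription with
    time-delayed reaction products (a Gillespie algorithm extended with a
    waitlist), and inference of the duration of promoter open complex
    formation from RNA-count time series sampled at fixed intervals. The
    sampled process is approximated as a time-homogeneous Markov chain whose
    stationary distribution and transition matrix are estimated by
    simulation with kernel smearing; grid log-likelihoods are summarized by
    a quadratic fit as a truncated normal posterior. Includes an additive
    Gaussian measurement-noise model and tools to rerun the reference
    simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
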