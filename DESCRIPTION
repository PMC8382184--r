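Package: ictogenicity
Title: Brain Network Ictogenicity from Phase-Oscillator Seizure Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates seizure transitions of the stochastic theta (SNIC
    phase-oscillator) model on weighted functional brain networks and
    quantifies network-level seizure propensity as brain network
    ictogenicity (BNI), the area under the curve of seizure-time fraction
    against cortical excitability. Per-node contributions are scored by
    virtual node removal (node ictogenicity, NI, and its normalised form
    nNI). Functional networks are built from multichannel regional time
    series via theta-band (4-8 Hz) phase-locking values corrected with
    iterative amplitude adjusted Fourier transform (IAAFT) surrogates,
    zero-phase-lag rejection and shortest-path edge pruning. Includes a
    synthetic-data generator for planted networks, coupled oscillatory
    signals and two-group cohorts, plus the nonparametric group statistics
    used in ictogenicity studies: Mann-Whitney U with z effect sizes,
    Friedman tests, a bootstrap null for nNI profiles with
    Benjamini-Hochberg control, and cross-validated logistic-regression
    MVPA with permutation testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
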