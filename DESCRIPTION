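Package: gaitsignatures
Title: Gait Signatures: Recurrent-Network Latent Dynamics of Walking Across Speeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds low-dimensional "gait signatures" from continuous
    multi-channel treadmill gait time series: a compact LSTM sequence model is
    trained to predict all trials one step ahead, its per-time-step hidden
    states are reduced by principal component analysis and phase-averaged over
    the gait cycle to yield one signature loop per trial. The package bundles a
    synthetic multi-subject, multi-speed cohort generator with known ground
    truth, gait-event detection from vertical ground reaction forces,
    spatiotemporal and discrete biomechanical variables, a seeded linear-SVM
    individual-identification experiment, a classical multidimensional-scaling
    gait map with intra-/inter-individual distance statistics, random-intercept
    mixed-effects models of signature position versus belt speed with a
    hierarchical leave-one-subject-out bootstrap, and Pearson correlation
    analyses relating signature shifts to balance ability and spatiotemporal
    changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    e1071,
    lme4,
    lmerTest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
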