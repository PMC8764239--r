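Package: tinnconn
Title: Connectivity-Feature Analysis and Classification of Resting-State EEG
Version: 0.1.0
Authors@R:
    person("tinnconn", "developers", email = "tinnconn@example.org", role = c("aut", "cre"))
Description: Tools for recognizing tinnitus laterality from resting-state
    multichannel EEG. Implements a full analysis pipeline: synthetic EEG
    generation with controlled class-conditional connectivity structure,
    zero-phase preprocessing (notch, band-pass, re-referencing, channel
    selection, epoching), four functional-connectivity estimators
    (phase-locking value, phase lag index, Pearson correlation, histogram
    plug-in transfer entropy) plus band-rhythm and power-spectral-density
    features, cross-validated classifiers (linear SVM with leave-one-out and
    10-fold CV, a two-hidden-layer MLP, and a CNN-LSTM), and group-level
    statistics (per-pair difference maps, one-way ANOVA, Kruskal-Wallis,
    and multidimensional-scaling channel clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
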