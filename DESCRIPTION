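Package: ihclamp
Title: Current-Clamp Simulation, Feature Extraction and I_h Parameter
    Fitting for CA1 Pyramidal Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing somatic current-clamp recordings of
    hippocampal CA1 pyramidal neurons and their reduced biophysical models.
    Simulates passive + hyperpolarization-activated (I_h, HCN) membrane
    responses of single-compartment or ball-and-stick neurons, extracts the
    standard electrophysiological feature catalogue (input resistance,
    resting potential, membrane time constant fitted to the sag peak, sag
    amplitude, action-potential shape, spike counts and instantaneous
    frequencies), fits passive and I_h kinetic parameters simultaneously
    against families of hyperpolarizing traces by seeded multi-start
    Levenberg-Marquardt least squares, generates labelled synthetic
    patch-clamp cohorts with known ground truth, classifies feature tables
    by genotype or age with bagged and boosted tree ensembles under 10-fold
    cross-validation, and runs per-feature, per-current two-group statistics
    with normality-based test routing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    randomForest,
    xgboost,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
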