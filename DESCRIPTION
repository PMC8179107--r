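Package: kinloops
Title: Kinetic Analysis of Slow Protein Loop Dynamics with Markov State
    Models and NMR Relaxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to identify and characterize slow conformational
    dynamics of protein loops from molecular dynamics ensembles and NMR
    relaxation data.  Implements exhaustive C-alpha pairwise-distance
    featurization with occupancy-based pruning, time-lagged independent
    component analysis (tICA), an iterative tICA-correlation feature
    selection procedure that discovers kinetic anchor residues,
    microstate Markov state models with reversible maximum-likelihood
    estimation, hidden-Markov-model coarse-graining into metastable
    macrostates with bootstrap population uncertainties and mean first
    passage times, comparison of two conformational ensembles in a
    shared kinetic coordinate space, and Lipari-Szabo model-free
    analysis of backbone amide R1/R2/NOE relaxation rates including
    R2/R1 timescale classification.  A synthetic-data generator with
    planted two-loop Markov switching kinetics and forward-modelled
    relaxation rates provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
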