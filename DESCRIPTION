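Package: antioxpep
Title: Sequence-Based Prediction of Antioxidant Peptide Activity
Version: 0.1.0
Authors@R:
    person("antioxpep", "developers", email = "antioxpep@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the free-radical-scavenging (FRS) and
    metal-chelating activity of short peptides (2-30 residues) directly from
    sequence. Provides a dual-output convolutional neural network trained
    with a focal loss, a sequence-identity k-nearest-neighbour baseline,
    homology-aware benchmark construction (Needleman-Wunsch identity
    redundancy filtering, matched-length random negatives, balanced fivefold
    homology partitions), nested cross-validated evaluation with
    MCC-optimal thresholding, residue-composition proportion tests, and
    application modes that scan or proteolytically digest proteins and rank
    the resulting peptides by predicted activity. A deterministic synthetic
    benchmark generator with planted compositional signal makes the whole
    pipeline testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
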