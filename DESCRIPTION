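Package: mlploc
Title: Multi-Label Protein Subcellular Localization with GAN-Based Class Rebalancing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular localization of multi-label proteins from
    evolutionary sequence profiles under severe class imbalance. Parses
    PSI-BLAST position-specific scoring matrices (PSSMs) and discretizes them
    into fixed 20x20 residue-composition features; rebalances minority
    localization classes by training a distance-regularized generative
    adversarial network that synthesizes minority-class feature matrices; and
    classifies with a multi-label DeepFM (parallel factorization-machine and
    deep components) trained under a thresholded exponential ranking loss.
    Includes the five standard multi-label evaluation metrics (Hamming loss,
    one-error, coverage, ranking loss, average precision), a synthetic
    imbalanced-dataset generator, k-fold cross-validation with fold-restricted
    rebalancing, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
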