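Package: asdmlc
Title: Imbalance-Aware Ensemble Classification with Adaptive Synthetic
    Oversampling and Particle Swarm Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Classification pipeline for imbalanced tabular data: ADASYN
    oversampling that allocates synthetic minority samples by local learning
    difficulty, min-max normalization, wrapper feature selection by binary
    particle swarm optimization with per-dimension velocity equalization,
    and a probability-averaging ensemble of an adaptive neuro-fuzzy
    inference system (first-order Sugeno), a probabilistic neural network,
    and clustering-based decision trees. Includes stratified k-fold
    evaluation with all stages fit inside each training fold, a
    with/without-selection ablation driver, loaders for CSV, ARFF and KEEL
    data files, and a synthetic-data generator with controlled class
    imbalance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    foreign,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
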