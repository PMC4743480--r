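Package: pgpcspr
Title: Classification Structure-Property Relationship Models for
    P-glycoprotein-Interacting Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for building interpretable binary
    classifiers of P-glycoprotein inhibitors and substrates from molecular
    descriptors. Provides dataset curation from SMILES (canonicalization,
    molecular-weight filtering, duplicate and overlapping-class removal),
    computation of seven interpretable 2D descriptors, collinearity-based
    feature pruning at a Pearson correlation cutoff, fuzzy C-means
    undersampling of the majority class with performance-driven cluster
    selection, a gain-ratio decision-tree inducer with if-then rule
    extraction plus neural-network and support-vector learners, and
    four-metric validation (accuracy, sensitivity, specificity, Matthews
    correlation coefficient) under stratified 10-fold cross-validation and
    a PCA-stratified 85/15 split. A seeded synthetic-data generator
    emulates the statistical structure of descriptor tables so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    igraph,
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
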