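Package: funpred
Title: Per-Term Support Vector Machine Prediction of Gene Ontology Annotations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A homology-independent framework for predicting Gene Ontology
    (GO) molecular function and biological process annotations of protein
    sequences from feature-based support vector machine (SVM) classifiers.
    Builds per-term training sets from an annotation corpus under strict
    eligibility rules, partitions proteins into homology-aware equal-size
    cross-validation groups, selects kernels and feature groups by
    MCC-optimised grid search with greedy feature-group elimination,
    calibrates decision values into posterior probabilities with a Platt
    sigmoid, and labels models with a two-tier reliability flag. Includes
    a full assessment suite: CAFA-style precision-recall curves and Fmax,
    a relaxed ancestor/descendant matching variant, information-content
    estimation, simGIC semantic similarity and combined COGIC scoring,
    plus synthetic fixture generators for ontologies, proteomes,
    annotation tables, feature matrices and homology block structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
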