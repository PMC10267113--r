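Package: mutddg
Title: Mutation-Induced Protein-Ligand Binding Free-Energy Changes from
    Drug-Sensitivity Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving mutation-induced protein-ligand binding
    free-energy changes (ddG) from cell-line drug-sensitivity screens.
    Parses and classifies protein mutation strings, curates screen tables
    into ddG-labelled samples via the RT*ln(IC50 ratio) relation, computes
    wild-type to mutant biochemical feature deltas from protein-ligand
    complex structures (ligand descriptors, amino-acid-change features,
    mutation-environment shells, interaction profiles), summarizes
    mutation statistics against codon-frequency expectations, and runs a
    scenario-based machine-learning benchmark (RMSE, Pearson, AUPRC) with
    a pluggable estimator contract. A synthetic-data module generates
    screens with planted ddG, toy protein-ligand complexes with exact
    geometry, and feature tables with linear signal for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ChemmineR,
    ChemmineOB,
    Biostrings,
    rpart,
    randomForest,
    ranger,
    e1071,
    glmnet,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
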