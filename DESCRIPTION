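Package: ayurnet
Title: Two-Branch Screening of Traditional-Medicine Formulae for
    Antibacterial Plant Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nominates candidate antibacterial medicinal plants from
    binary formula-by-plant incidence tables with a per-formula
    antibiotic-class label. A network branch links formulae whose
    Minkowski distance falls below a threshold, clusters the graph with
    an overlapping density-based algorithm (DPClusO), scores clusters by
    antibiotic-class composition and extracts plants recurring in
    dominant clusters. A machine-learning branch compares seven
    classifiers under variance filtering, PCA and SMOTE class
    balancing, tunes a random forest by grid search, and ranks plants
    by permutation importance. Final candidates are the intersection of
    the two branches after plant-name normalization. A synthetic-data
    generator with planted signal plants makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    igraph,
    nnet,
    ranger,
    rlang,
    rpart,
    stats,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
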