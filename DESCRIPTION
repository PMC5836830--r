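Package: pairkern
Title: Pairwise-Kernel Prediction of Heterodimeric Protein Complexes
Version: 0.1.0
Authors@R:
    person("pairkern", "maintainers", email = "pairkern@example.org",
           role = c("aut", "cre"))
Description: Predicts heterodimeric protein complexes from a weighted
    protein-protein interaction network and per-protein annotations
    (domain composition, phylogenetic profiles, subcellular
    localization).  Protein-level Min, MinMax and scale-normalized Min
    kernels are lifted to protein-pair kernels with the metric learning
    pairwise kernel (MLPK) and the tensor product pairwise kernel
    (TPPK), combined with a seven-dimensional network/domain feature
    vector, and classified with a class-weighted C-support vector
    machine on precomputed Gram matrices under stratified k-fold
    cross-validation.  Includes a seeded synthetic-data generator that
    plants heterodimer edges and shared domain-composition templates,
    readers and writers for the tab-separated exchange formats, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
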