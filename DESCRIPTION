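Package: cqdiff
Title: Differential Analysis of Circulating miRNA qPCR Panels with Robust
    Permutation Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for deciding whether circulating miRNA
    qPCR profiles differ between two small patient groups, built around the
    plasma/serum panel workflow: spike-in and hemolysis quality control
    (miR-23a/miR-451a dCq), reference-miRNA Cq normalization (2^-dCq),
    per-assay fold change, permutation Yuen-Welch trimmed-mean testing with
    Benjamini-Hochberg adjustment, dysregulation classification, and
    propensity-score 1:1 nearest-neighbour case-control matching. Includes a
    synthetic Cq-data generator with limit-of-detection censoring, hemolysis
    contamination and spike-in channels so every stage is testable without
    patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
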