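Package: triangulatr
Title: Decision-Level Integration of Conflicting Single-Cell Cluster Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles competing cluster annotations of the same single-cell
    dataset (different algorithms, resolutions, or modalities) at the level of
    individual cells. Every cluster in every annotation set is scored with
    stability metrics (centroid reassignment fraction, TF-IDF marker
    exclusivity, cross-validated logistic-regression recall); each cell is then
    assigned to the annotation with the highest exact Shapley value in a
    coalitional game over the metric ranks, and unstable winner clusters are
    pruned and their cells reclassified by nearest stable centroid. Includes
    multimodal normalization and concatenation helpers (log counts-per-10k,
    centered log-ratio for antibody tags), entropy-based agreement metrics
    (homogeneity, completeness, V-measure), and a group-structured
    negative-binomial count simulator with annotation perturbation recipes for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
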