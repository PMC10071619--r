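Package: connectopy
Title: Connectome-Based Group Classification, Anomaly Counting and Hub-Shift
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for case-control analysis of brain connectomes on the
    379-region HCP-MMP1 parcellation: subject-level Pearson functional
    connectivity matrices and their unique-pair feature vectors,
    cross-validated gradient-boosted-tree classification with signed
    SHAP-style feature importance aggregated over large-scale networks,
    control-referenced median-absolute-deviation anomaly counting per
    network, and weighted PageRank centrality with control-median rank-shift
    detection on streamline-count structural connectomes. Includes a
    synthetic-cohort generator with planted functional and structural
    effects for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
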