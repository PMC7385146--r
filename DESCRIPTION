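Package: cytoboot
Title: Bootstrapped Metaclustering and Group Classification for Longitudinal Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-arm, multi-timepoint single-cell mass
    cytometry (CyTOF) studies. Implements downsampling-free bootstrapped
    metaclustering (per-sample k-means with k = sqrt(N/2), repeated k-means
    metaclustering of the pooled cluster centers), cluster-level frequency and
    baseline-subtracted signaling features, repeated leave-group-out
    random-forest classification with ROC/AUC and rank-sum testing per
    timepoint, a PCA immune-cell atlas annotated with per-cluster two-group
    statistics, and Isomap embedding of innate and adaptive immune
    trajectories. Includes a synthetic-study generator with known population
    structure and plantable arm-specific effects so the full pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ranger,
    vegan,
    igraph,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
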