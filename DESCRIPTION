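Package: zonecor
Title: Transcriptional Correspondence Between Zones of Layered Cartilage Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping transcriptional correspondence between the
    zones of two spatially stratified cartilage tissues (articular and growth
    plate cartilage) profiled on different microarray platforms. Implements
    quantile normalization and median-polish summarization, per-zone-pair
    spatial differential expression calling (fold-change plus
    Benjamini-Hochberg false discovery rate), cross-platform directional
    gene-list overlap testing with Pearson chi-square statistics and
    Holm-Sidak family correction, marker-set zonal localization, exploratory
    sample-structure analyses (PCA, hierarchical clustering, z-score
    heat-map matrices), and delta-delta-CT relative quantification with
    repeated-measures zone statistics for qPCR validation. A seeded,
    truth-annotated synthetic-data generator emulates the two-platform zonal
    study design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
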