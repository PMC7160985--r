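Package: slcpath
Title: Pathway-Level Comparison of Septic Shock and Cancer Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Permutation-based pathway enrichment scoring of case/control
    transcriptome studies, robust multi-study pathway filtering, hierarchical
    clustering of study-level pathway signatures to segregate cancers into
    sepsis-like (SLC) and other (CA) groups, pathway-overlap network analysis
    with degree and betweenness centrality, per-patient pathway scores from
    paired tumour/normal expression, cross-validated SVM and neural-network
    group classification, median-split Kaplan-Meier survival screening, and
    2x2 contingency analysis. Includes a synthetic-data generator that plants
    concordant pathway shifts across disease groups so the full pipeline is
    testable without external repositories.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    e1071,
    nnet,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
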