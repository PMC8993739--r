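Package: myoGRN
Title: Core Skeletal-Muscle Gene Regulatory Network Reconstruction and
    Transcriptome Maturity Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a core gene regulatory network of human skeletal
    muscle from co-expression, functional-annotation and interaction-graph
    evidence, derives muscle-restricted and differentiation-stage reference
    gene sets, and scores differential-expression tables of reprogrammed
    cells against these references to assess their maturity and
    heterogeneity. Includes a from-scratch weighted co-expression core
    (soft-threshold selection against scale-free topology, topological
    overlap, average-linkage module detection, eigengene merging), twelve
    topological hub centralities with rank-based hub filtering, stage-onset
    persistence classification of differentiation profiles, and synthetic
    data generators that plant known structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
biocViews: NetworkInference, GeneExpression, Transcriptomics,
    GraphAndNetwork, GeneSetEnrichment
RoxygenNote: 7.3.3
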