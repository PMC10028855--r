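Package: sigcompass
Title: Scoring, Quality Control and Comparison of Cancer Transcriptional Signatures
Version: 0.1.0
Authors@R:
    person("sigcompass", "developers", email = "sigcompass@example.org",
           role = c("aut", "cre"))
Description: A curated, queryable catalog of cancer transcriptional
    signatures together with a scoring engine that produces per-sample,
    per-cell or per-spot scores from bulk, single-cell or spatial
    expression data. Signatures are normalized into six method families
    (weighted sum, z-score mean, up/down contrast, single-sample rank
    enrichment, immunophenoscore composite, consensus-centroid subtyping).
    Includes signature reliability metrics for sparse data, cross-signature
    comparison (correlation clustering with silhouette-based model
    selection, survival association, group tests), simulators for bulk,
    single-cell and spatial data with planted signal, and a command-line
    interface tying the pieces into a reproducible workflow.
License: AGPL-3
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    methods,
    tools,
    survival,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
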