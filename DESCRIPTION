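Package: tmrnet
Title: Consensus Transcriptional Master Regulator Inference Across
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers transcriptional master regulators (TMRs) shared by two
    independent tumor/normal expression cohorts. Reconstructs mutual-
    information regulon networks by adaptive-partitioning estimation with
    permutation-calibrated significance thresholds, data-processing-
    inequality pruning and bootstrap consolidation; scores regulator
    activity against the tumor-versus-normal signature with a permutation
    null; combines cohort evidence by Fisher's method and inverse-variance-
    weighted effect-size meta-analysis; builds a motif-plus-coexpression
    supported TMR-TMR hierarchy with degree-quantile hub calls; and runs
    regulon-level over-representation analysis. A synthetic-data generator
    with planted regulons, activity shifts and promoter motif instances
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    edgeR,
    Biostrings,
    fgsea,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
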