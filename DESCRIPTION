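Package: neurodevatlas
Title: Developmental Single-Cell Neuronal Atlas Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing developmental single-cell gene-expression
    atlases of compact nervous systems. Implements pseudobulk aggregation with
    per-gene dynamic expression thresholding calibrated against a binary
    ground truth (TPR/FPR/FDR with stratified BCa bootstrap confidence
    intervals), cross-stage differential-expression filtering with stability
    and Jaccard metrics and fold-enrichment testing, regulon-based
    transcription-factor activity scoring via multivariate linear models,
    maturation-index correlation analysis on 2-D embeddings, construction and
    cross-stage comparison of spatially constrained neuropeptide
    ligand-receptor signaling networks, and connectome-conditioned gene
    enrichment with Welch tests. A seed-controlled synthetic-data generator
    supplies inputs with the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
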