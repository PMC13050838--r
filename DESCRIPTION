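Package: seqfuse
Title: Dual-Branch Convolutional and Bidirectional LSTM Classification of
    Protein Sequences
Version: 0.1.0
Authors@R:
    person("Seqfuse", "Developers", email = "seqfuse@example.org",
           role = c("aut", "cre"))
Description: Tools for binary classification of protein sequences with a
    dual-branch one-dimensional convolutional network followed by a
    bidirectional LSTM, fused with handcrafted descriptors (pseudo amino
    acid composition and dipeptide composition) and a pooled residue
    embedding. Includes FASTA ingestion and validation, greedy
    identity-based redundancy filtering over exact global alignment,
    stratified splitting, z-score feature normalization, seeded training
    with Adam, plateau learning-rate scheduling and early stopping,
    confusion-matrix metrics with bootstrap confidence intervals and
    paired significance tests, integrated-gradients attribution, a
    planted-motif synthetic corpus generator, and an end-to-end
    experiment/ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
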