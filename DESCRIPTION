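Package: spsdinfer
Title: Visibility and Ambiguity Analysis for Logic-Based Gene Regulatory
    Network Inference
Version: 0.1.0
Authors@R:
    person("spsdinfer", "developers", email = "spsdinfer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying what single-gene perturbation experiments
    can and cannot reveal about the Boolean logic of gene regulation. The
    package enumerates all non-degenerate k-input Boolean functions, builds
    single-perturbation state diagrams (SPSDs) under knock-down (D) and
    knock-down/over-expression (DO) regimes with transcriptome-only,
    transcriptome+PPI, and transcriptome+cis-element+PPI evidence
    integration, computes visibility and full-visibility probabilities,
    counts the Boolean functions consistent with observed transitions
    (ambiguity), evaluates single- and multi-step perturbation designs, and
    identifies the Boolean function of a target gene from perturbation
    records combined with cis-element and protein-protein interaction
    evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
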