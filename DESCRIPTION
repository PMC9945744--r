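Package: l3npred
Title: Normalized L3 Link Prediction for Protein-Protein Interaction Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Link prediction for protein-protein interaction (PPI) networks
    built on the L3 principle: two proteins joined by many paths of length
    three (and few paths of length two) are likely to interact directly.
    Implements the NormalizedL3 (L3N and L3N') predictors, which score a
    candidate pair by how closely its length-3 neighborhood resembles an
    ideal L3 graph under pluggable set-similarity metrics (simple ratio and
    Jaccard), together with the baseline predictors CN, RA, AA, CRA, L3,
    CH2_L3 and Sim. Also provides ideal-L3-graph perturbation simulations
    (compatible-edge removal, incompatible-edge insertion), a Monte-Carlo /
    k-fold precision-recall evaluation harness with negative-PPI injection,
    a duplication-mutation synthetic interactome generator, edge-list
    ingestion with dataset-cleaning accounting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
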