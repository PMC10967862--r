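Package: synergnet
Title: Graph Neural Network Prediction of Anticancer Drug Synergy on
    Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for classifying drug pairs as synergistic or
    antagonistic against cancer cell lines. Drug-pair/cell-line instances
    are encoded as featured graphs on a shared human protein-protein
    interaction (PPI) network, with 218-dimensional node features combining
    differential expression, copy-number category, mutation indicators,
    drug-protein association scores, and gene-ontology embeddings.
    Knowledge-based graph reduction by constrained edge contraction yields
    compact per-instance quotient graphs; a drug action/chemical similarity
    (DACS) filter generates augmented training instances by substituting
    similar drugs; a two-module graph convolutional network with jumping
    knowledge aggregation and dual global pooling performs graph-level
    classification; a vectorization plus random-forest baseline and a
    leakage-safe stratified cross-validation harness complete the stack.
    A synthetic-data generator with a planted label rule makes every stage
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
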