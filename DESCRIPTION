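Package: coelnet
Title: Protein Interaction Networks from Co-Elution Data and Genomic Data
    Integration Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interaction networks from protein
    correlation profiling (co-elution / co-fractionation) experiments using
    dataset-derived chromatogram features and a naive Bayes co-complex
    classifier trained on reference complexes, optionally supplemented with
    external genomic features (coexpression, phylogenetic profiles,
    domain-domain interactions, literature co-citation, gene fusion, gene
    neighborhood, and interologous interactions). Provides an evaluation
    battery for any predicted network: neighbor-voting functional
    connectivity, interaction novelty, time-split validation of novel
    interactions, bias toward highly studied proteins, global clustering
    coefficient, and robustness to incomplete genomic data. Includes a
    synthetic-data generator emulating the statistical structure of
    co-elution studies so the full pipeline is testable without external
    downloads, and an experiment runner that sweeps feature combinations and
    computes trend statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
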