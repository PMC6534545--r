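Package: goscape
Title: Gene Ontology DAG Refinement, Leveled Layouts and Enrichment Power Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with Gene Ontology style directed acyclic
    graphs: parsing OBO ontologies and gene2go annotation tables, true-path
    annotation propagation, redundancy-removing DAG refinement, anchor-based
    focus and context subgraph induction, three leveled graph layouts
    (root-bound, leaf-bound, and the annotation-aware buoyant layout computed
    by a bubble-float algorithm), context silhouettes and binder orderings.
    Includes a power-analysis simulator for gene set enrichment testing under
    self-contained and competitive null hypotheses (Simes combination and
    hypergeometric tests with false discovery rate control), and a
    zero-inflated negative binomial single-cell RNA-seq count simulator with
    ontology-derived cell-type signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    tools,
    withr,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
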