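Package: lcadag
Title: Least Common Ancestor Structure and Simplification of Rooted
    Phylogenetic Networks and DAGs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing least common ancestor (LCA) structure in
    rooted directed acyclic graphs (DAGs) and phylogenetic networks. Provides
    a validated DAG data model with hardwired clusters and shortcut removal,
    a linear-time LCA algorithm for leaf subsets together with a
    definition-faithful brute-force oracle, recognizers for structural
    classes (path-cluster-comparability, cluster-lca, no-three-overlaps,
    regular, LCA-relevant and lca-relevant DAGs), and the vertex-suppression
    operator used to simplify any DAG into an LCA-relevant or lca-relevant
    one while preserving ancestry, clusters and LCA sets. Includes Hasse
    diagram construction for cluster systems, cluster restrictions,
    simplification maps satisfying the standard transformation axioms,
    generators for galled trees and random DAGs, and vertex-cover reduction
    gadgets for adversarial testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
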