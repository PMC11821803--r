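# lcadag

Least common ancestor (LCA) structure and simplification of rooted
phylogenetic networks and general DAGs.

## The problem

Rooted phylogenetic networks — and, more generally, rooted directed acyclic
graphs — model evolutionary histories with reticulate events that trees
cannot express. Networks inferred from genomic data are frequently tangled:
they contain inner vertices that are not the least common ancestor of *any*
set of taxa, so nothing in the observable data (the leaves) witnesses their
existence. `lcadag` is for anyone who works with such DAGs and wants to

* query LCA structure: the set `LCA_G(A)` of minimal common ancestors of a
  leaf set `A`, which in a DAG may be empty, a singleton, or several
  incomparable vertices;
* recognise the structural classes that organise this theory —
  path-cluster-comparability (PCC), the cluster-lca properties (CL,
  strong-CL), regularity, N3O (no three pairwise overlapping clusters,
  satisfied by trees and galled trees), and LCA-/lca-relevance;
* simplify a DAG so that **every** surviving vertex is an LCA (or the
  unique LCA) of some leaf set, while provably preserving the original
  taxa, ancestry, clusters and LCA answers.

## The model in brief

For a DAG `G` on taxa `X`, the cluster of a vertex is its set of descendant
leaves, `C(v) = { x in X : x ⪯ v }`. A vertex `v` is a *k*-LCA vertex if
`v ∈ LCA_G(A)` for some `A ⊆ X` with `|A| = k`, and a *k*-lca vertex if it
is the unique such minimal ancestor. `G` is **LCA-relevant** (resp.
**lca-relevant**) when every vertex qualifies for some `k`; equivalently, no
edge joins two vertices with the same cluster (resp. cluster inclusion
coincides with ancestry). The central tool is the vertex-suppression
operator `⊖`: `G ⊖ v` deletes `v` and joins each parent of `v` to each
child of `v`. Suppressing the non-LCA vertices (computed via
`v ∈ LCA_G(C(v))`, checkable in linear time per vertex) yields the unique
minimum simplification satisfying the preservation contract (S0)–(S5):
same leaf set, no new vertices or clusters, identical ancestry among
survivors, identical (unique) LCA sets. The maps
`φ_LCA(G) = (G ⊖ W(G))⁻` and `φ_lca` (shortcuts removed at the end)
additionally satisfy the standard simplification axioms: fixpoint on
already-simplified DAGs, equivariance under taxon relabelling, and
commutation with the cluster restriction `G ≀ Y`. Deciding whether a vertex
is a *k*-LCA vertex for a *prescribed* `k` is NP-complete in general — the
package ships the vertex-cover gadget constructions as adversarial test
generators — but polynomial for N3O DAGs, where dedicated fast paths apply.

## Worked example

A galled tree with root `rho` above `u1` and `u2`, an extra edge
`(u1, u2)`, and leaves `x1, x2, x3`. Its root is not the unique LCA of any
leaf set, because `u1` also has the full cluster `{x1,x2,x3}`:

```r
library(lcadag)
G <- fixture_dag("galled_cor710")
is_lca_relevant(G)
#> <property_report> lca-relevant: violated
#>   witness: rho u1

rep <- make_lca_relevant(G)
rep
#> <dag_simplification> mode lca: removed 1 of 6 vertices
#>   removed: rho
#>   S0:ok S1:ok S2:ok S3:ok S4:ok S5:?

dag_edges(rep$output)
#>      parent child
#> [1,] "u1"   "u2"
#> [2,] "u1"   "x1"
#> [3,] "u2"   "x2"
#> [4,] "u2"   "x3"
```

The witness pair `(rho, u1)` is an edge whose endpoints carry the same
cluster — exactly the certificate that the DAG is not LCA-relevant. The
simplification removes only `rho`; the flags record that the leaf set
(S1), vertex set (S2), ancestry (S3), clusters (S0) and defined unique
LCAs (S4) were verified to be preserved on this instance (`S5:?` means the
full-LCA-set flag is not applicable to the unique-LCA mode). The output is
lca-relevant, and after shortcut removal it coincides with the Hasse
diagram of the cluster system:

```r
dag_cluster_isomorphic(remove_shortcuts(rep$output), hasse(cluster_system(G)))
#> [1] TRUE
```

A command-line wrapper with `check`, `lca`, `simplify`, `hasse`,
`restrict` and `generate` subcommands is installed under
`inst/cli/lcadag`.

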