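---
title: "LCA-relevant simplification of phylogenetic networks and DAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LCA-relevant simplification of phylogenetic networks and DAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcadag)
```

## The objects and the question

A rooted DAG `G` on a taxon set `X` has the out-degree-0 vertices as its
leaves (`X` itself) and carries, at every vertex, the *hardwired cluster*
`C(v)`: the leaves reachable from `v`. Clusters are what sequence data can
actually support, so inner vertices ought to be witnessed by them. The
sharpest form of such support is being a least common ancestor: `v` is in
`LCA_G(A)` when it is an ancestor of every taxon in `A` and no descendant
of `v` is. In a general DAG this set can be empty (two taxa may have no
common ancestor at all when the DAG has several roots) or contain several
incomparable vertices; `lca_G(A)` denotes the unique member when there is
exactly one.

`lcadag` answers four connected questions. Is `v` an LCA of a *given*
`A`? Is `v` an LCA of *some* `A`, possibly of prescribed size `k`? Which
DAGs have only such supported vertices (LCA-relevant / lca-relevant)?
And how can an arbitrary DAG be reduced to one of these classes while
provably keeping its information content?

The package deliberately treats DAGs, not just single-rooted networks, as
first-class: multiple roots and disconnected inputs occur naturally as
intermediate objects (and in the two-root counterexamples below), and no
super-root is ever added implicitly.

## Deciding LCA membership: the sweep and its oracle

`lca_set()` implements a single pass over a topological order. For a query
`A` it maintains the residue `A \ C(v)` per vertex — for a leaf this is
`A` minus the leaf itself, for an inner vertex the intersection of its
children's residues, which is correct because a cluster is the union of
its children's clusters. A vertex is reported exactly when its own residue
is empty and every child's residue is non-empty; this is the
child-cluster characterization of LCA membership. The cost is
`O((|V|+|E|)·|A|)`.

The package keeps a second, deliberately naive implementation,
`lca_bruteforce()`, that intersects ancestor sets and filters the minimal
elements. It exists purely as an independent oracle: the test suite
compares the two on an exhaustive enumeration of all DAGs on up to five
vertices (up to relabelling, via "staircase" edge subsets over a fixed
vertex order) with every query of size at most three, and on 2,000 seeded
random DAGs of up to twelve vertices. These sizes were chosen so that the
exhaustive layer is genuinely exhaustive while the whole suite stays in
the minutes range; agreement is exact, not approximate.

From the sweep, everything else about single vertices follows: `v` is an
LCA vertex of *some* query size if and only if `v ∈ LCA_G(C(v))`, and a
unique-LCA vertex iff `v = lca_G(C(v))`, so `is_LCA_vertex()` and
`is_lca_vertex()` are one sweep each. The admissible query sizes of a
vertex always form an interval ending at `|C(v)|`
(`lca_size_interval()`).

## Explicit k: hardness, the work bound, and the N3O fast path

Deciding "is `v` a k-LCA vertex?" for a `k` given as input is NP-complete;
the package therefore refuses to pretend otherwise. For general DAGs,
`is_k_LCA()`/`is_k_lca()` enumerate the size-`k` subsets of `C(v)` under a
work bound (`max_subsets`, default one million candidate subsets) and
raise a typed error (`lcadag_work_bound`) when the bound would be
exceeded — an explicit refusal rather than a silent approximation.

On DAGs whose cluster system has no three pairwise overlapping clusters
(N3O — the class containing all rooted trees and galled trees) the
problem collapses: an inner vertex is a k-LCA vertex for *some* `k ≥ 2`
iff it is one for *every* `2 ≤ k ≤ |C(v)|`, so the explicit-k test reduces
to the some-k test plus a range check. The N3O verdict is computed once
per DAG (a cubic scan over distinct cluster triples) and cached inside the
object; `dag` values are immutable, so the cache can never go stale. The
vertex-cover gadget generators (`vc_gadget()`) exist to exercise the
*hard* branch: they encode Vertex Cover instances so that a distinguished
vertex is a k-LCA (k-lca) vertex exactly when a size-`k` cover exists, and
the suite verifies this equivalence against brute-force cover enumeration
for every connected non-star graph on four to six vertices (taken up to
isomorphism, since both sides of the equivalence are
isomorphism-invariant).

## The simplification operator and its contract

`ominus(G, v)` removes `v` and joins each parent to each child; leaves and
roots are simply deleted. The operator commutes with itself, so
suppressing a vertex set is order-free. When only inner vertices are
suppressed, the result keeps the leaf set, the ancestry among survivors,
and every surviving vertex's cluster — the preservation contract
(S0)–(S3); when the suppressed vertices are non-LCA (non-lca) vertices,
the (unique) LCA answers are preserved as well (S5, resp. S4).

Two algorithms build on this:

* `make_LCA_relevant()` evaluates its condition — `v ∉ LCA_G(C(v))` —
  entirely on the **input** DAG and suppresses all failures at once. This
  is sound because the LCA sets themselves are invariant under each of
  these suppressions, and the removal set is the *unique minimum* set
  whose suppression gives an LCA-relevant DAG satisfying (S0)–(S5). The
  output keeps the exact cluster system and stays connected if the input
  was. The test suite confirms minimality by exhaustive search over all
  smaller candidate sets on every corpus DAG with at most ten vertices.
* `make_lca_relevant()` must re-evaluate `v ≠ lca(C(v))` on the
  **current** DAG at each step, because suppressing one non-unique-LCA
  vertex can turn another into a unique LCA. Its result therefore depends
  on the processing order, which the theory leaves open. The package fixes
  vertices in the deterministic topological order of the input with
  lexicographic tie-breaks — ancestors first. This choice is not only
  reproducible: on the two-root chain example (`fixture_dag("fig6", n)`)
  it removes the redundant extra root before the chain vertices it
  shadows, so the full cluster system survives, whereas the opposite order
  would collapse it to singletons plus `X`. On inputs with the CL or PCC
  property the order does not matter: the removal set provably coincides
  with the LCA-mode set, clusters are preserved, and the shortcut-free
  output is the Hasse diagram of the cluster system (compared in the
  tests via the canonical cluster labelling).

Every simplification returns a report whose flags record which parts of
the contract were *verified on that instance*. S0–S3 are always checked
exactly. S4/S5 quantify over all leaf subsets, which is exponential, so
the report verifies them over all queries of size at most three and only
when the DAG has at most nine leaves (`max_verify_leaves`); otherwise the
flag is `NA` — the guarantee still holds by the theory, but the package
does not claim to have re-measured it. The acceptance-level tests
additionally run a *full* (all subset sizes) contract check on small
corpora.

## Simplification as a transformation: the axioms

With `W(G)` the non-LCA vertices, `phi_LCA(G) = remove_shortcuts(G ⊖ W(G))`
maps any DAG into the class of shortcut-free LCA-relevant DAGs. Under the
cluster restriction `cluster_restriction(G, Y)` — the relabelled Hasse
diagram of the non-empty traces `C ∩ Y` — this map satisfies the three
simplification axioms: (P1) it fixes every member of its image class,
(P2) it commutes with taxon relabelling, (P3) it commutes with
restriction. It is also idempotent. `phi_lca()` does the same with the
non-unique-LCA vertices; on CL (hence also PCC) inputs it coincides with
`phi_LCA()` and inherits the axioms. Without CL it is still well-defined
and often informative, so the function proceeds with a warning rather than
refusing; (P3) genuinely fails there, and the suite reproduces the
canonical counterexample (the two-root chain restricted to its first two
taxa gives an edgeless DAG one way and a cherry the other).

Isomorphism in these statements is checked two ways. Where both sides have
pairwise distinct clusters (all lca-relevant outputs, all Hasse diagrams)
the canonical cluster labelling `v ↦ C(v)` decides isomorphism exactly and
cheaply (`dag_cluster_isomorphic()`). Where clusters can repeat — e.g.
LCA-relevant outputs under (P2) — a small backtracking search
(`dag_isomorphic()`) with leaves pinned to their labels is used; it is a
test utility, not an attempt at scalable graph isomorphism.

## Synthetic data: what it emulates and what it does not

The generators exist to exercise the algorithms, not to simulate
evolution. `random_dag()` draws a layered DAG: inner vertices in a fixed
topological order joined forward with probability `edge_density` (default
0.3, the mid-range between near-trees and dense tangles at the corpus
sizes), leaves attached to one or more random parents, and childless inner
vertices repaired so the leaf count is exactly as requested. It produces
multi-rooted, sometimes disconnected DAGs on purpose — the counterexamples
in this theory live there. `random_galled_tree()` grows a random
phylogenetic tree by recursive partition (2–3 children per vertex) and
rewires up to `n_galls` inner vertices into galls — two internally
disjoint paths from the vertex to a new reticulation, with the original
subtrees hung off the path vertices — yielding single-rooted, phylogenetic
networks whose N3O property is asserted at generation time. Corpus sizes
throughout the suite (three to eight taxa, up to roughly a dozen vertices;
hundreds of seeded instances per property) were fixed once so that
exhaustive sub-checks (all queries, all smaller removal sets, all deletion
orders) remain feasible; they are small worlds, and passing tests show
correctness of the combinatorics, not statistical behaviour on
genome-scale networks. Real inferred networks differ in ways the
generators do not model: branch lengths, biased reticulation placement,
and inference noise have no counterpart here, but none of these affect the
purely structural guarantees being tested. All randomness is drawn from a
stream fixed by an explicit `seed`, and the caller's RNG state is restored
afterwards.

Worked fixtures (`fixture_dag()`) are reconstructed from explicit textual
constructions only — the cherry, the two-maximal-vertex `pq` example, the
non-regular relabelled Hasse diagram of `{{x},{x,y}}`, the two-root chain
family, the galled-tree root counterexample and its `x4` repair, and the
index-set chain — never from a drawing, so every fixture is exactly
reproducible.

## Numerical and design choices

* **Determinism.** Kahn's algorithm with lexicographic tie-breaking fixes
  one topological order per DAG; every order-dependent computation
  (Algorithm output, serialization, CLI output) inherits it. Two equal
  DAGs serialize byte-identically.
* **Degenerate inputs.** Single-vertex DAGs, edgeless DAGs, multi-rooted
  and disconnected DAGs are all valid. An empty LCA set and an undefined
  unique LCA are ordinary return values (`character(0)`,
  `NA_character_`), never errors; errors are reserved for malformed input
  (cycles, self-loops, unknown vertices, non-leaf queries) and carry
  typed condition classes.
* **Suppressing everything is refused**: `ominus()` requires at least one
  surviving vertex, and leaves are never candidates for removal in either
  simplification algorithm (a leaf is always the unique LCA of itself).
* **Index-set relevance** (`is_I_relevant()`): an index set without 1 is
  answered `FALSE` immediately with a leaf as witness (leaves are only
  ever 1-LCA vertices) rather than treated as an error, since it is a
  legitimate, decidable query.
* **Recognizer witnesses.** Every `FALSE` verdict ships a counterexample
  (vertex, pair, edge, or cluster triple) that the tests re-validate
  against the defining condition, so a wrong verdict cannot hide behind a
  boolean.
* **Regularity** is decided by the structural route (shortcut-free, PCC,
  no out-degree-1 vertex) and cross-checked against the definitional
  route (cluster map is an isomorphism onto the Hasse diagram); the suite
  asserts the two agree on every corpus DAG.

## Known limitations

* The explicit-k machinery is exponential off the N3O class by necessity;
  the work bound makes this a visible, typed failure rather than a slow
  surprise.
* Finding a globally minimum removal set when the uniqueness guarantee
  does not apply (general inputs in unique-LCA mode), or maximising the
  number of preserved clusters, is out of scope; the package exposes only
  the deterministic algorithms with their proven contracts.
* `dag_isomorphic()` is exponential in the worst case and intended for
  the small instances that arise in tests.
* Extended-Newick import/export and any visualisation are out of scope;
  JSON and TSV edge lists are the interchange formats (DAGs are not
  trees, so Newick proper cannot represent them).
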