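test_that("vertex suppression joins parents to children", {
  P <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_equal(unname(dag_edges(ominus(P, "b"))), rbind(c("a", "c")))

  cherry <- fixture_dag("cherry")
  H <- ominus(cherry, "w")
  expect_setequal(dag_vertices(H), c("x", "y"))
  expect_equal(nrow(dag_edges(H)), 0L)

  expect_error(ominus(cherry, c("w", "x", "y")), class = "lcadag_empty_result")
  expect_error(ominus(cherry, "zz"), class = "lcadag_unknown_vertex")
  expect_dag_equal(ominus(cherry, character(0)), cherry)
})

test_that("suppression of distinct vertices commutes", {
  set.seed(4204)
  for (s in 1:10) {
    G <- random_dag(4, 4, 0.35, seed = 2500 + s)
    inner <- setdiff(dag_vertices(G), leaves(G))
    if (length(inner) < 2L) next
    pick <- sample(inner, 2L)
    expect_dag_equal(ominus(ominus(G, pick[1]), pick[2]),
                     ominus(ominus(G, pick[2]), pick[1]))
  }
})

test_that("suppressing inner vertices preserves order, leaves and clusters", {
  set.seed(4205)
  for (s in 1:10) {
    G <- random_dag(4, 5, 0.35, seed = 2600 + s)
    inner <- setdiff(dag_vertices(G), leaves(G))
    W <- sample(inner, min(2L, length(inner)))
    H <- ominus(G, W)
    expect_setequal(leaves(H), leaves(G))
    for (v in dag_vertices(H)) {
      expect_setequal(dag_cluster(H, v), dag_cluster(G, v))
      for (u in dag_vertices(H)) {
        expect_equal(is_ancestor(H, u, v), is_ancestor(G, u, v))
      }
    }
  }
})

test_that("fig6 suppression reproduces both caption outcomes", {
  F6 <- fixture_dag("fig6", n = 4)
  X <- leaves(F6)
  chain <- setdiff(dag_vertices(F6), c(X, "r"))
  H1 <- ominus(F6, chain)
  keys1 <- vapply(cluster_system(H1)$clusters, paste, "", collapse = ",")
  expect_setequal(keys1, c(X, paste(sort(X), collapse = ",")))
  H2 <- ominus(F6, "r")
  expect_true(setequal(
    vapply(cluster_system(H2)$clusters, paste, "", collapse = ","),
    vapply(cluster_system(F6)$clusters, paste, "", collapse = ",")
  ))
  expect_true(dag_cluster_isomorphic(H2, hasse(cluster_system(F6))))
})

test_that("make_LCA_relevant removes exactly the non-LCA vertices", {
  Tree <- hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
  repT <- make_LCA_relevant(Tree)
  expect_length(repT$removed, 0L)
  expect_dag_equal(repT$output, Tree)

  G <- fixture_dag("galled_cor710")
  repG <- make_LCA_relevant(G)
  expect_equal(repG$removed, "rho")
  H <- repG$output
  expect_equal(roots(H), "u1")
  expect_setequal(dag_children(H, "u1"), c("u2", "x1"))
  expect_setequal(dag_children(H, "u2"), c("x2", "x3"))
  expect_true(is_LCA_relevant(H)$holds)
  expect_true(is_phylogenetic(H))
  expect_true(all(repG$flags[c("S0", "S1", "S2", "S3", "S4", "S5")]))

  expect_length(make_LCA_relevant(fixture_dag("fig6", n = 3))$removed, 0L)
})

test_that("make_LCA_relevant preserves clusters, connectivity and LCA sets", {
  for (s in 1:12) {
    G <- random_dag(4, 5, 0.35, seed = 2700 + s)
    rep <- make_LCA_relevant(G)
    H <- rep$output
    expect_true(is_LCA_relevant(H)$holds)
    expect_true(is_phylogenetic(H))
    expect_setequal(lcadag:::cluster_keys(H), lcadag:::cluster_keys(G))
    expect_true(all(rep$flags[c("S0", "S1", "S2", "S3", "S4", "S5")]))
    # connectivity preserved
    expect_equal(dag_connected(H), dag_connected(G))
  }
})

test_that("make_lca_relevant processes ancestors first and yields lca-relevance", {
  cherry <- fixture_dag("cherry")
  repC <- make_lca_relevant(cherry)
  expect_length(repC$removed, 0L)
  expect_dag_equal(repC$output, cherry)

  F6 <- fixture_dag("fig6", n = 3)
  repF <- make_lca_relevant(F6)
  expect_equal(repF$removed, "r") # the redundant root goes first
  expect_setequal(lcadag:::cluster_keys(repF$output), lcadag:::cluster_keys(F6))
  expect_true(is_lca_relevant(repF$output)$holds)

  G <- fixture_dag("galled_cor710")
  repG <- make_lca_relevant(G)
  expect_equal(repG$removed, "rho")
  expect_true(is_lca_relevant(repG$output)$holds)
  expect_true(is_phylogenetic(repG$output))
})

test_that("on CL/PCC inputs Algorithm 3 matches Algorithm 2 and the Hasse diagram", {
  for (G in corpus_dags(n_random = 12L)) {
    rep3 <- make_lca_relevant(G, verify_lca_sets = FALSE)
    expect_true(is_lca_relevant(rep3$output)$holds)
    expect_true(is_phylogenetic(rep3$output))
    if (dag_connected(G)) expect_true(dag_connected(rep3$output))
    if (has_cl(G)$holds || has_pcc(G)$holds) {
      rep2 <- make_LCA_relevant(G, verify_lca_sets = FALSE)
      expect_setequal(rep3$removed, rep2$removed)
      expect_setequal(lcadag:::cluster_keys(rep3$output), lcadag:::cluster_keys(G))
      expect_true(dag_cluster_isomorphic(remove_shortcuts(rep3$output),
                                         hasse(cluster_system(G))))
    }
  }
})

test_that("hasse builds the cover digraph of the examples", {
  Tree <- hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
  expect_setequal(paste(dag_edges(Tree)[, 1], dag_edges(Tree)[, 2]),
                  c("{x,y,z} {x,y}", "{x,y,z} z", "{x,y} x", "{x,y} y"))
  expect_true(is_phylogenetic(Tree))
  expect_true(is_hierarchy(cluster_system(Tree)))

  H <- hasse(list("x", c("x", "y")), relabel = FALSE)
  expect_equal(nrow(dag_edges(H)), 1L)
  expect_error(hasse(list("x", c("x", "y")), relabel = TRUE),
               class = "lcadag_not_grounded")

  expect_true(dag_cluster_isomorphic(hasse(list("x", "y", c("x", "y"))),
                                     fixture_dag("cherry")))
})

test_that("strong-CL DAGs are Hasse diagrams plus shortcuts, and conversely", {
  set.seed(4206)
  for (s in 1:10) {
    # forward: random DAG -> test consistency
    G <- random_dag(3, 4, 0.4, seed = 2900 + s)
    if (has_strong_cl(G)$holds) {
      expect_true(dag_cluster_isomorphic(remove_shortcuts(G),
                                         hasse(cluster_system(G))))
    }
    # converse: Hasse diagram plus random shortcuts has strong-CL
    H <- hasse(cluster_system(random_galled_tree(5, 1, seed = 2950 + s)))
    em <- dag_edges(H)
    extra <- NULL
    for (u in dag_vertices(H)) {
      nonchild <- setdiff(dag_vertices(H), c(u, dag_children(H, u)))
      desc <- nonchild[vapply(nonchild, function(w) is_ancestor(H, u, w), NA)]
      if (length(desc) > 0L) extra <- rbind(extra, c(u, sample(desc, 1L)))
    }
    if (!is.null(extra)) {
      Hplus <- dag(dag_vertices(H), rbind(em, extra))
      expect_true(has_strong_cl(Hplus)$holds)
    }
  }
})

test_that("phi_LCA satisfies the simplification axioms", {
  set.seed(4207)
  # (P1): shortcut-free LCA-relevant DAGs are fixed
  F6 <- fixture_dag("fig6", n = 3)
  expect_dag_equal(phi_LCA(F6), F6)
  Tree <- hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
  expect_dag_equal(phi_LCA(Tree), Tree)
  # idempotence
  for (s in 1:6) {
    G <- random_dag(4, 5, 0.35, seed = 3100 + s)
    H <- phi_LCA(G)
    expect_dag_equal(phi_LCA(H), H)
    expect_true(is_LCA_relevant(H)$holds)
    expect_equal(nrow(shortcuts(H)), 0L)
    expect_setequal(lcadag:::cluster_keys(H), lcadag:::cluster_keys(G))
  }
  # (P2): equivariance under leaf permutation
  for (s in 1:6) {
    G <- random_dag(3, 4, 0.4, seed = 3200 + s)
    X <- leaves(G)
    perm <- stats::setNames(sample(X), X)
    lhs <- phi_LCA(permute_leaves(G, perm))
    rhs <- permute_leaves(phi_LCA(G), perm)
    expect_true(dag_isomorphic(lhs, rhs))
  }
  # (P3): commutation with the cluster restriction
  for (s in 1:8) {
    G <- random_dag(4, 5, 0.35, seed = 3300 + s)
    Y <- sample(leaves(G), sample(length(leaves(G)), 1))
    expect_true(dag_cluster_isomorphic(phi_LCA(cluster_restriction(G, Y)),
                                       cluster_restriction(phi_LCA(G), Y)))
  }
})

test_that("phi_lca equals phi_LCA under CL but can break (P3) without it", {
  Tree <- hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
  expect_dag_equal(phi_lca(Tree), Tree)

  G <- fixture_dag("galled_cor710")
  expect_dag_equal(phi_lca(G), phi_LCA(G))

  F6 <- fixture_dag("fig6", n = 3)
  expect_warning(H <- phi_lca(F6), "cluster-lca")
  expect_setequal(dag_vertices(H), leaves(F6))
  expect_equal(nrow(dag_edges(H)), 0L)

  # the documented (P3) counterexample: restrict to Y = {x1, x2}
  Y <- c("x1", "x2")
  lhs <- cluster_restriction(suppressWarnings(phi_lca(F6)), Y)
  rhs <- suppressWarnings(phi_lca(cluster_restriction(F6, Y)))
  expect_equal(nrow(dag_edges(lhs)), 0L)         # edgeless on {x1, x2}
  expect_equal(nrow(dag_edges(rhs)), 2L)         # the cherry on {x1, x2}
  expect_false(dag_cluster_isomorphic(lhs, rhs))
})

test_that("hierarchical CL inputs collapse to the unique phylogenetic tree", {
  for (s in 1:8) {
    T0 <- random_galled_tree(5, 0, seed = 3400 + s)
    G <- inject_redundancy(T0, seed = 3450 + s)
    expect_true(has_cl(G)$holds)
    expect_true(is_hierarchy(cluster_system(G)))
    H1 <- phi_LCA(G)
    H2 <- suppressWarnings(phi_lca(G))
    expect_true(dag_cluster_isomorphic(H1, hasse(cluster_system(G))))
    expect_true(dag_cluster_isomorphic(H1, H2))
    expect_true(is_phylogenetic(H1))
    expect_true(all(vapply(dag_vertices(H1), function(v) {
      length(dag_parents(H1, v)) <= 1L
    }, NA))) # a tree
  }
})

test_that("cluster restriction behaves on the boundary cases", {
  set.seed(4208)
  Tree <- hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
  expect_true(dag_cluster_isomorphic(cluster_restriction(Tree, leaves(Tree)), Tree))
  single <- cluster_restriction(Tree, "y")
  expect_equal(dag_vertices(single), "y")
  expect_error(cluster_restriction(Tree, character(0)),
               class = "lcadag_empty_restriction")
  expect_error(cluster_restriction(Tree, "nope"),
               class = "lcadag_invalid_restriction")
  for (s in 1:5) {
    G <- random_dag(3, 4, 0.4, seed = 3500 + s)
    Y <- sample(leaves(G), 2)
    expect_true(is_regular(cluster_restriction(G, Y))$holds)
  }
})

test_that("suppressing an inner vertex preserves N3O", {
  for (s in 1:8) {
    G <- random_galled_tree(5, 2, seed = 3600 + s)
    inner <- setdiff(dag_vertices(G), leaves(G))
    for (v in inner) {
      expect_true(is_n3o(ominus(G, v))$holds)
    }
  }
})
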