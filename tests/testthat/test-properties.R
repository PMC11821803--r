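test_that("PCC holds on trees and fails with a checkable witness otherwise", {
  Tree <- hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
  expect_true(has_pcc(Tree)$holds)

  F6 <- fixture_dag("fig6", n = 3)
  r <- has_pcc(F6)
  expect_false(r$holds)
  # witness pair: nested clusters but incomparable vertices
  u <- r$witness[1]; v <- r$witness[2]
  cu <- dag_cluster(F6, u); cv <- dag_cluster(F6, v)
  expect_true(all(cu %in% cv) || all(cv %in% cu))
  expect_false(is_ancestor(F6, u, v) || is_ancestor(F6, v, u))

  TwoRoots <- dag(c("r1", "r2", "x", "y"),
                  rbind(c("r1", "x"), c("r1", "y"), c("r2", "x"), c("r2", "y")))
  expect_false(has_pcc(TwoRoots)$holds)
})

test_that("CL and strong-CL recognise the fixture hierarchy", {
  cherry <- fixture_dag("cherry")
  expect_true(has_strong_cl(cherry)$holds)
  expect_true(has_cl(cherry)$holds)

  G <- fixture_dag("galled_cor710")
  expect_true(has_cl(G)$holds)
  sr <- has_strong_cl(G)
  expect_false(sr$holds)
  expect_equal(sr$witness, "rho")

  F6 <- fixture_dag("fig6", n = 3)
  expect_false(has_cl(F6)$holds)
})

test_that("PCC implies CL, and CL pins lca(C(v)) below v with equal cluster", {
  for (G in corpus_dags(n_random = 15L)) {
    if (has_pcc(G)$holds) expect_true(has_cl(G)$holds)
    if (has_cl(G)$holds) {
      for (v in dag_vertices(G)) {
        u <- lca(G, dag_cluster(G, v))
        expect_false(is.na(u))
        expect_true(is_ancestor(G, v, u))
        expect_setequal(dag_cluster(G, u), dag_cluster(G, v))
      }
    }
  }
})

test_that("N3O scan finds pairwise overlapping triples", {
  Tree <- hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
  expect_true(is_n3o(Tree)$holds)

  sys3 <- cluster_system(list("a", "b", "c", c("a", "b"), c("b", "c"),
                              c("a", "c"), c("a", "b", "c")))
  r <- is_n3o(sys3)
  expect_false(r$holds)
  expect_length(r$witness, 3L)
  w <- r$witness
  expect_true(lcadag:::sets_overlap(w[[1]], w[[2]]))
  expect_true(lcadag:::sets_overlap(w[[1]], w[[3]]))
  expect_true(lcadag:::sets_overlap(w[[2]], w[[3]]))

  expect_true(is_n3o(fixture_dag("fig6", n = 4))$holds)
})

test_that("both regularity routes agree and match the examples", {
  Tree <- hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
  expect_true(is_regular(Tree)$holds)
  hx <- fixture_dag("hasse_xy")
  expect_false(is_regular(hx)$holds)
  expect_false(is_regular(hx, "definition")$holds)
  # Hasse diagram of any grounded system is regular and phylogenetic
  sys <- cluster_system(list("a", "b", "c", "d", c("a", "b"), c("b", "c"),
                             c("a", "b", "c")))
  H <- hasse(sys)
  expect_true(is_regular(H)$holds)
  expect_true(is_phylogenetic(H))
  for (G in corpus_dags(n_random = 15L)) {
    expect_equal(is_regular(G)$holds, is_regular(G, "definition")$holds)
  }
})

test_that("LCA-relevance is the no-equal-adjacent-clusters condition", {
  expect_true(is_LCA_relevant(fixture_dag("fig6", n = 3))$holds)
  r <- is_LCA_relevant(fixture_dag("galled_cor710"))
  expect_false(r$holds)
  expect_setequal(r$witness, c("rho", "u1"))
  # an out-degree-1, in-degree-<=1 vertex forces failure
  Chain <- dag(c("a", "b", "x"), rbind(c("a", "b"), c("b", "x")))
  expect_false(is_LCA_relevant(Chain)$holds)
  # definitional check: every vertex an LCA vertex
  for (G in corpus_dags(n_random = 12L)) {
    def <- all(vapply(dag_vertices(G), function(v) is_LCA_vertex(G, v), NA))
    expect_equal(is_LCA_relevant(G)$holds, def)
  }
})

test_that("lca-relevance matches its equivalent characterizations", {
  Tree <- hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
  expect_true(is_lca_relevant(Tree)$holds)
  expect_false(is_lca_relevant(fixture_dag("fig6", n = 3))$holds)
  expect_true(is_lca_relevant(fixture_dag("galled_cor710_x4"))$holds)

  for (G in corpus_dags(n_random = 15L)) {
    a <- is_lca_relevant(G)$holds
    b <- has_strong_cl(G)$holds
    cc <- has_pcc(G)$holds && is_LCA_relevant(G)$holds
    keys <- vapply(cluster_system(G)$clusters, paste, "", collapse = "|")
    d <- has_pcc(G)$holds &&
      length(unique(lcadag:::cluster_keys(G))) == length(dag_vertices(G))
    def <- all(vapply(dag_vertices(G), function(v) is_lca_vertex(G, v), NA))
    expect_equal(a, b)
    expect_equal(a, cc)
    expect_equal(a, d)
    expect_equal(a, def)
  }
})

test_that("regular = shortcut-free + lca-relevant; lca-relevant => |V| = |C|", {
  for (G in corpus_dags(n_random = 15L)) {
    expect_equal(is_regular(G)$holds,
                 nrow(shortcuts(G)) == 0L && is_lca_relevant(G)$holds)
    if (is_lca_relevant(G)$holds) {
      expect_equal(length(dag_vertices(G)), length(cluster_system(G)$clusters))
      expect_true(is_phylogenetic(G))
      expect_false(any(vapply(dag_vertices(G), function(v) {
        length(dag_children(G, v)) == 1L
      }, NA)))
    }
  }
})

test_that("index-set relevance delegates, fast-paths and witnesses correctly", {
  G4 <- fixture_dag("galled_cor710_x4")
  full <- seq_along(leaves(G4))
  expect_equal(is_I_relevant(G4, full, "lca")$holds, is_lca_relevant(G4)$holds)
  expect_equal(is_I_relevant(G4, full, "LCA")$holds, is_LCA_relevant(G4)$holds)
  expect_true(is_I_relevant(G4, c(1, 2), "lca")$holds)

  ch <- fixture_dag("chain_hasse", indices = c(1, 3))
  expect_true(is_I_relevant(ch, c(1, 3), "lca")$holds)

  # 1 must be admissible: leaves are only ever 1-lca vertices
  r <- is_I_relevant(G4, c(2, 3), "lca")
  expect_false(r$holds)
  expect_true(r$witness %in% leaves(G4))
  expect_error(is_I_relevant(G4, integer(0)), class = "lcadag_invalid_index_set")

  # N3O fast path equals the per-vertex enumeration oracle
  for (s in 1:6) {
    G <- random_galled_tree(5, 1, seed = 2100 + s)
    for (I in list(c(1, 2), c(1, 3), c(1, 2, 4))) {
      I <- I[I <= length(leaves(G))]
      for (mode in c("LCA", "lca")) {
        want <- all(vapply(dag_vertices(G), function(v) {
          any(vapply(I, function(k) oracle_is_k(G, v, k, mode == "lca"), NA))
        }, NA))
        expect_equal(is_I_relevant(G, I, mode)$holds, want)
      }
    }
  }
})
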