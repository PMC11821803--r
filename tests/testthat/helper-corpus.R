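# Shared corpus builders and independent oracles for the test suite.

# All DAGs on n ordered vertices with edges only from lower to higher index.
# Up to relabelling this family covers every DAG on n vertices, and all the
# properties tested against it are label-invariant.
staircase_dags <- function(n) {
  labs <- sprintf("v%d", seq_len(n))
  pairs <- if (n >= 2L) t(utils::combn(n, 2L)) else matrix(integer(0), ncol = 2L)
  m <- nrow(pairs)
  out <- vector("list", 2^m)
  for (mask in seq_len(2^m) - 1L) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    em <- cbind(labs[pairs[sel, 1L]], labs[pairs[sel, 2L]])
    out[[mask + 1L]] <- dag(labs, em)
  }
  out
}

all_small_queries <- function(X, kmax = 3L) {
  out <- list()
  for (k in seq_len(min(kmax, length(X)))) {
    out <- c(out, utils::combn(X, k, simplify = FALSE))
  }
  out
}

# fixtures plus assorted random instances, reused by several files
corpus_dags <- function(n_random = 30L, seed0 = 100L) {
  fixtures <- list(
    fixture_dag("cherry"),
    fixture_dag("pq_dag"),
    fixture_dag("hasse_xy"),
    fixture_dag("fig6", n = 2),
    fixture_dag("fig6", n = 3),
    fixture_dag("fig6", n = 5),
    fixture_dag("galled_cor710"),
    fixture_dag("galled_cor710_x4"),
    fixture_dag("chain_hasse", indices = c(1, 3)),
    hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
  )
  randoms <- lapply(seq_len(n_random), function(i) {
    random_dag(n_inner = 2L + (i %% 5L), n_leaves = 3L + (i %% 4L),
               edge_density = 0.2 + 0.1 * (i %% 4L), seed = seed0 + i)
  })
  galled <- lapply(seq_len(max(0L, n_random %/% 3L)), function(i) {
    random_galled_tree(n_leaves = 4L + (i %% 3L), n_galls = 1L + (i %% 2L),
                       seed = seed0 + 1000L + i)
  })
  c(fixtures, randoms, galled)
}

# Definition-level oracle for explicit-k vertex tests: enumerate all leaf
# subsets of size k. Independent of the is_k_* code paths.
oracle_is_k <- function(G, v, k, unique) {
  X <- leaves(G)
  if (k > length(X)) return(FALSE)
  any(utils::combn(X, k, FUN = function(A) {
    m <- lca_bruteforce(G, A)
    if (unique) identical(m, v) else v %in% m
  }))
}

# igraph-based reachability oracle
igraph_reach <- function(G) {
  em <- dag_edges(G)
  g <- igraph::graph_from_data_frame(
    as.data.frame(em), directed = TRUE,
    vertices = data.frame(name = dag_vertices(G))
  )
  d <- igraph::distances(g, mode = "out")
  is.finite(d)[dag_vertices(G), dag_vertices(G), drop = FALSE]
}

expect_dag_equal <- function(G, H) {
  expect_true(dag_equal(G, H))
}

# weak connectivity of a dag (undirected reachability)
dag_connected <- function(G) {
  vs <- dag_vertices(G)
  n <- length(vs)
  if (n <= 1L) return(TRUE)
  em <- dag_edges(G)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  for (k in seq_len(nrow(em))) {
    ra <- find(match(em[k, 1L], vs))
    rb <- find(match(em[k, 2L], vs))
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, 0L))) == 1L
}

# Take a tree and inject redundant out-degree-1 vertices (edge subdivisions)
# and shortcuts. Clusters, ancestry among original vertices, hierarchy and
# CL status are all preserved, so the result is a CL DAG with hierarchical
# cluster system that is no longer lca-relevant.
inject_redundancy <- function(T0, seed) {
  set.seed(seed)
  em <- dag_edges(T0)
  vs <- dag_vertices(T0)
  n_sub <- sample(1:2, 1)
  for (i in seq_len(n_sub)) {
    k <- sample(nrow(em), 1)
    s <- sprintf("s%03d", i)
    vs <- c(vs, s)
    em <- rbind(em[-k, , drop = FALSE], c(em[k, 1L], s), c(s, em[k, 2L]))
  }
  G <- dag(vs, em)
  # add a couple of shortcuts (edges to strict non-child descendants)
  extra <- NULL
  for (u in sample(dag_vertices(G))) {
    cand <- setdiff(dag_vertices(G), c(u, dag_children(G, u)))
    cand <- cand[vapply(cand, function(w) is_ancestor(G, u, w), NA)]
    if (length(cand) > 0L) {
      extra <- rbind(extra, c(u, sample(cand, 1L)))
      if (!is.null(extra) && nrow(extra) >= 2L) break
    }
  }
  if (!is.null(extra)) G <- dag(dag_vertices(G), rbind(dag_edges(G), extra))
  G
}

# all permutations of 1:n as a list of integer vectors
combinat_perms <- function(n) {
  if (n <= 1L) return(list(seq_len(n)))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in combinat_perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
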