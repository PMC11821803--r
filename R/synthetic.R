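#' Worked example DAGs
#'
#' Returns the small DAGs used throughout the documentation and tests. All
#' of them are reconstructed from explicit textual constructions, not from
#' drawings:
#'
#' * `"cherry"`: a single root `w` with leaf children `x`, `y`.
#' * `"pq_dag"`: two maximal vertices `p`, `q` with `C(p) = {x,y}` and
#'   `C(q) = {x,z}`; the leaves `y` and `z` have no common ancestor, so
#'   `LCA({y,z})` is empty.
#' * `"hasse_xy"`: the relabelled Hasse diagram of `{{x},{x,y}}`, a single
#'   edge whose two vertices share the cluster `{x}` — the standard
#'   non-phylogenetic, non-regular example.
#' * `"fig6"` (parameter `n >= 2`): the Hasse diagram of the chain system
#'   `{{x1,x2}, {x1,x2,x3}, ..., X}` plus all singletons, with a second
#'   root `r` adjacent to every leaf. Every query of size >= 2 has exactly
#'   two LCAs (`r` and a chain vertex), so the DAG is LCA-relevant but not
#'   lca-relevant. Chain vertices are labelled `v1, ..., v(n-1)` with
#'   `C(vi) = {x1, ..., x(i+1)}`.
#' * `"galled_cor710"`: the galled tree with root `rho`, children `u1`,
#'   `u2`, extra edge `(u1, u2)`, `u1` above leaf `x1` and `u2` above
#'   leaves `x2`, `x3`. It is phylogenetic but its root is not a unique
#'   LCA of any leaf set.
#' * `"galled_cor710_x4"`: the same with an extra leaf `x4` attached to
#'   the root, which makes the galled tree lca-relevant.
#' * `"chain_hasse"` (parameter `indices`, a size set containing 1): the
#'   Hasse diagram of `{{xj} : j <= max(I)}` together with
#'   `{x1..xj} : j in I, j > 1`, which is I-lca-relevant.
#'
#' @param name fixture name, see above.
#' @param n chain length parameter for `"fig6"`.
#' @param indices admissible size set for `"chain_hasse"`.
#' @return A `dag`.
#' @examples
#' lca_set(fixture_dag("pq_dag"), c("y", "z"))
#' @export
fixture_dag <- function(name, n = NULL, indices = NULL) {
  switch(
    name,
    cherry = dag(c("w", "x", "y"), rbind(c("w", "x"), c("w", "y"))),
    pq_dag = dag(c("p", "q", "x", "y", "z"),
                 rbind(c("p", "x"), c("p", "y"), c("q", "x"), c("q", "z"))),
    hasse_xy = dag(c("{x,y}", "x"), rbind(c("{x,y}", "x"))),
    fig6 = fixture_fig6(n),
    galled_cor710 = dag(
      c("rho", "u1", "u2", "x1", "x2", "x3"),
      rbind(c("rho", "u1"), c("rho", "u2"), c("u1", "u2"),
            c("u1", "x1"), c("u2", "x2"), c("u2", "x3"))
    ),
    galled_cor710_x4 = dag(
      c("rho", "u1", "u2", "x1", "x2", "x3", "x4"),
      rbind(c("rho", "u1"), c("rho", "u2"), c("u1", "u2"),
            c("u1", "x1"), c("u2", "x2"), c("u2", "x3"), c("rho", "x4"))
    ),
    chain_hasse = fixture_chain_hasse(indices),
    stop_lcadag(sprintf("unknown fixture: %s", name), "unknown_fixture")
  )
}

fixture_fig6 <- function(n) {
  if (is.null(n) || n < 2L) {
    stop_lcadag("fig6 requires n >= 2", "invalid_params")
  }
  n <- as.integer(n)
  xs <- paste0("x", seq_len(n))
  vs <- if (n >= 2L) paste0("v", seq_len(n - 1L)) else character(0)
  edges <- rbind(c("v1", "x1"), c("v1", "x2"))
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      edges <- rbind(edges, c(paste0("v", i), paste0("v", i - 1L)),
                     c(paste0("v", i), paste0("x", i + 1L)))
    }
  }
  for (x in xs) edges <- rbind(edges, c("r", x))
  dag(c("r", vs, xs), edges)
}

fixture_chain_hasse <- function(indices) {
  if (is.null(indices) || !(1L %in% indices)) {
    stop_lcadag("chain_hasse requires an index set containing 1", "invalid_params")
  }
  I <- sort(unique(as.integer(indices)))
  m <- max(I)
  xs <- paste0("x", seq_len(m))
  cls <- as.list(xs)
  for (j in setdiff(I, 1L)) cls <- c(cls, list(xs[seq_len(j)]))
  hasse(cluster_system(cls), relabel = TRUE)
}

#' Undirected graphs for the vertex-cover gadgets
#'
#' A minimal undirected-graph value type used as input to [vc_gadget()]:
#' a vertex label set and a set of 2-element edges (no loops, no
#' multi-edges).
#'
#' @param vertices character vector of labels.
#' @param edges two-column character matrix (or list of pairs) of
#'   undirected edges.
#' @return An object of class `ugraph`.
#' @export
ugraph <- function(vertices, edges) {
  vertices <- sort(unique(as.character(vertices)), method = "radix")
  em <- normalize_edges(edges)
  if (nrow(em) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    if (any(em[, 1L] == em[, 2L])) stop_lcadag("loop in undirected graph", "invalid_edge")
    if (!all(c(em) %in% vertices)) stop_lcadag("unknown vertex in edge", "unknown_vertex")
    em <- t(apply(em, 1L, sort))
    em <- unique(em)
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  structure(list(vertices = vertices, edges = em), class = "ugraph")
}

#' @export
print.ugraph <- function(x, ...) {
  cat(sprintf("<ugraph> %d vertices, %d edges\n", length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Does a graph have a vertex cover of a given size?
#'
#' Brute-force enumeration over all vertex subsets of size `k`; a cover
#' must touch every edge. Used as the independent reference side of the
#' gadget equivalences.
#'
#' @param H a [ugraph()].
#' @param k integer cover size.
#' @return `TRUE` or `FALSE`.
#' @export
vertex_cover_exists <- function(H, k) {
  stopifnot(inherits(H, "ugraph"))
  k <- as.integer(k)
  if (k >= length(H$vertices)) return(TRUE)
  if (nrow(H$edges) == 0L) return(TRUE)
  any(utils::combn(H$vertices, k, FUN = function(W) {
    all(H$edges[, 1L] %in% W | H$edges[, 2L] %in% W)
  }))
}

#' Vertex-cover reduction gadgets
#'
#' Encodes a Vertex Cover instance as an LCA question, following the
#' reductions that establish NP-completeness of the explicit-k tests. The
#' input graph must have at least 4 vertices, at least 2 edges, and no
#' vertex contained in every edge (no star), so that the constructions are
#' well-formed.
#'
#' * `mode = "LCA"`: the relabelled Hasse diagram of the clustering system
#'   consisting of all singletons, the complements `V \ e` of the edges,
#'   and `V` itself. The result is a regular network with root `"rho"` and
#'   one inner vertex `r_e` per edge (labelled by the sorted endpoints,
#'   e.g. `"r_1|3"`); `rho` is a k-LCA vertex iff the graph has a vertex
#'   cover of size `k` (for `1 < k <= |V|`).
#' * `mode = "lca"`: the same construction without the root; instead each
#'   `r_e` receives two private leaves `x1_e`, `x2_e` (making it a 2-lca
#'   vertex), and an extra vertex `"rstar"` is attached to all original
#'   leaves. `rstar` is a k-lca vertex iff the graph has a vertex cover of
#'   size `k`.
#'
#' @param H a [ugraph()] satisfying the constraints above.
#' @param mode `"LCA"` or `"lca"`.
#' @return A `dag`.
#' @examples
#' H <- ugraph(as.character(1:4),
#'             rbind(c("1", "2"), c("2", "3"), c("3", "4"), c("4", "1")))
#' G <- vc_gadget(H, "LCA")
#' is_k_LCA(G, "rho", 2)
#' @export
vc_gadget <- function(H, mode = c("LCA", "lca")) {
  mode <- match.arg(mode)
  stopifnot(inherits(H, "ugraph"))
  V <- H$vertices
  E <- H$edges
  if (length(V) < 4L || nrow(E) < 2L) {
    stop_lcadag("gadget input needs >= 4 vertices and >= 2 edges", "gadget_constraint")
  }
  universal <- vapply(V, function(v) all(E[, 1L] == v | E[, 2L] == v), NA)
  if (any(universal)) {
    stop_lcadag("gadget input must not be a star (no vertex in every edge)",
                "gadget_constraint")
  }
  estr <- apply(E, 1L, paste, collapse = "|")
  r_e <- paste0("r_", estr)
  edges <- NULL
  for (i in seq_len(nrow(E))) {
    for (v in setdiff(V, E[i, ])) edges <- rbind(edges, c(r_e[i], v))
  }
  if (mode == "LCA") {
    for (re in r_e) edges <- rbind(edges, c("rho", re))
    return(dag(c("rho", r_e, V), edges))
  }
  x1 <- paste0("x1_", estr)
  x2 <- paste0("x2_", estr)
  for (i in seq_len(nrow(E))) {
    edges <- rbind(edges, c(r_e[i], x1[i]), c(r_e[i], x2[i]))
  }
  for (v in V) edges <- rbind(edges, c("rstar", v))
  dag(c("rstar", r_e, V, x1, x2), edges)
}

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Random DAG and galled-tree generators
#'
#' `random_dag()` draws a layered random DAG: `n_inner` inner vertices are
#' placed in a fixed topological order and each forward pair is joined
#' with probability `edge_density`; each of the `n_leaves` leaves then
#' receives one or more random inner parents, and any inner vertex left
#' childless is attached to a random leaf so the leaf set has exactly the
#' requested size. `random_galled_tree()` first grows a random
#' phylogenetic tree on the taxa and then rewires up to `n_galls` inner
#' vertices into galls (two internally disjoint root-to-reticulation
#' paths whose side vertices carry the original subtrees); the generated
#' networks are phylogenetic, have a single root, and satisfy N3O (this is
#' asserted at generation time).
#'
#' All randomness is drawn from a stream fixed by `seed`; the caller's RNG
#' state is left untouched, and equal seeds give identical DAGs.
#'
#' @param n_inner number of inner vertices.
#' @param n_leaves number of leaves (taxa).
#' @param edge_density probability of each forward inner-inner edge, in
#'   `(0, 1]`.
#' @param n_galls maximum number of galls to insert.
#' @param seed integer seed.
#' @return A `dag`.
#' @export
random_dag <- function(n_inner, n_leaves, edge_density = 0.3, seed = 1L) {
  if (n_inner < 1L || n_leaves < 1L) {
    stop_lcadag("n_inner and n_leaves must be >= 1", "invalid_params")
  }
  if (edge_density <= 0 || edge_density > 1) {
    stop_lcadag("edge_density must be in (0, 1]", "invalid_params")
  }
  with_seed(seed, {
    inner <- sprintf("t%02d", seq_len(n_inner))
    lvs <- sprintf("x%02d", seq_len(n_leaves))
    edges <- NULL
    if (n_inner >= 2L) {
      for (i in seq_len(n_inner - 1L)) {
        for (j in seq.int(i + 1L, n_inner)) {
          if (stats::runif(1) < edge_density) {
            edges <- rbind(edges, c(inner[i], inner[j]))
          }
        }
      }
    }
    for (x in lvs) {
      np <- min(n_inner, 1L + stats::rbinom(1L, 2L, 0.3))
      for (p in sample(inner, np)) edges <- rbind(edges, c(p, x))
    }
    has_child <- inner %in% edges[, 1L]
    for (v in inner[!has_child]) {
      edges <- rbind(edges, c(v, sample(lvs, 1L)))
    }
    dag(c(inner, lvs), edges)
  })
}

#' @rdname random_dag
#' @export
random_galled_tree <- function(n_leaves, n_galls = 1L, seed = 1L) {
  if (n_leaves < 1L) stop_lcadag("n_leaves must be >= 1", "invalid_params")
  with_seed(seed, {
    xs <- sprintf("x%02d", seq_len(n_leaves))
    counter <- new.env(parent = emptyenv())
    counter$i <- 0L
    new_label <- function(prefix) {
      counter$i <- counter$i + 1L
      sprintf("%s%03d", prefix, counter$i)
    }
    edges <- NULL
    grow <- function(S) {
      if (length(S) == 1L) return(S)
      v <- new_label("v")
      nparts <- if (length(S) == 2L) 2L else sample(2:min(3L, length(S)), 1L)
      S <- sample(S)
      cuts <- sort(sample(seq_len(length(S) - 1L), nparts - 1L))
      parts <- split(S, findInterval(seq_along(S), cuts + 1L))
      for (p in parts) {
        child <- grow(p)
        edges <<- rbind(edges, c(v, child))
      }
      v
    }
    root <- grow(xs)
    if (n_leaves >= 2L && n_galls > 0L) {
      inner <- unique(edges[, 1L])
      picks <- sample(inner, min(n_galls, length(inner)))
      for (v in picks) {
        C <- edges[edges[, 1L] == v, 2L]
        if (length(C) < 2L) next
        C <- sample(C)
        b <- new_label("b")
        if (length(C) == 2L) {
          p1 <- new_label("p")
          side <- rbind(c(v, p1), c(p1, b), c(v, b), c(p1, C[1L]), c(b, C[2L]))
        } else {
          split_at <- sample(seq_len(length(C) - 1L), 1L)
          L <- C[seq_len(split_at)]
          B <- C[seq.int(split_at + 1L, length(C))]
          half <- ceiling(length(L) / 2)
          Lft <- L[seq_len(half)]
          Rgt <- L[-seq_len(half)]
          side <- NULL
          path_edges <- function(children) {
            prev <- v
            out <- NULL
            for (ch in children) {
              p <- new_label("p")
              out <- rbind(out, c(prev, p), c(p, ch))
              prev <- p
            }
            rbind(out, c(prev, b))
          }
          side <- rbind(side, path_edges(Lft))
          side <- rbind(side, if (length(Rgt) > 0L) path_edges(Rgt) else c(v, b))
          for (ch in B) side <- rbind(side, c(b, ch))
        }
        edges <- rbind(edges[edges[, 1L] != v, , drop = FALSE],
                       edges[edges[, 1L] == v & !(edges[, 2L] %in% C), , drop = FALSE],
                       side)
      }
    }
    G <- if (is.null(edges)) dag(xs) else dag(unique(c(edges)), edges)
    stopifnot(is_n3o(G)$holds)
    G
  })
}

#' Enumerate connected undirected graphs on n vertices
#'
#' Enumerates every connected graph on the labelled vertex set
#' `1, ..., n`; with `non_isomorphic = TRUE` (default) one representative
#' per isomorphism class is kept, using igraph's canonical permutation for
#' deduplication. Intended for exhaustive small-instance testing of the
#' vertex-cover gadgets (`n <= 6` is practical).
#'
#' @param n number of vertices (>= 2).
#' @param non_isomorphic keep one representative per isomorphism class.
#' @return List of [ugraph()] objects.
#' @export
all_connected_ugraphs <- function(n, non_isomorphic = TRUE) {
  stopifnot(n >= 2L, n <= 7L)
  pairs <- utils::combn(n, 2L)
  m <- ncol(pairs)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    sel <- bitwAnd(mask, 2L^(seq_len(m) - 1L)) > 0L
    if (sum(sel) < n - 1L) next # too few edges to be connected
    ep <- pairs[, sel, drop = FALSE]
    # union-find connectivity
    parent <- seq_len(n)
    find <- function(a) {
      while (parent[a] != a) a <- parent[a]
      a
    }
    for (k in seq_len(ncol(ep))) {
      ra <- find(ep[1L, k])
      rb <- find(ep[2L, k])
      if (ra != rb) parent[ra] <- rb
    }
    if (length(unique(vapply(seq_len(n), find, 0L))) > 1L) next
    if (non_isomorphic) {
      g <- igraph::graph_from_edgelist(t(ep), directed = FALSE)
      cp <- igraph::canonical_permutation(g)$labeling
      gc <- igraph::permute(g, cp)
      el <- igraph::as_edgelist(gc)
      el <- t(apply(el, 1L, sort))
      key <- paste(el[order(el[, 1L], el[, 2L]), ], collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
    }
    out[[length(out) + 1L]] <- ugraph(as.character(seq_len(n)),
                                      matrix(as.character(ep), nrow = 2L) |> t())
  }
  out
}
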