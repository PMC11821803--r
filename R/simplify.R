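#' Vertex suppression: the ominus operator
#'
#' `ominus(G, v)` removes vertex `v` and its incident edges and connects
#' every parent of `v` with every child of `v`. A leaf or root is simply
#' deleted together with its edges. The operator commutes with itself, so
#' suppressing a set `W` of vertices (given as a character vector) is
#' well-defined regardless of order. When the suppressed vertices are all
#' inner vertices, the result is a DAG on the same leaf set whose ancestor
#' relation, clusters and (for non-LCA vertices) LCA sets agree with those
#' of `G` on the surviving vertices.
#'
#' @param G a `dag`.
#' @param v character vector of vertices to suppress (a proper subset of
#'   the vertex set; empty is allowed and returns `G` unchanged).
#' @return A `dag`.
#' @examples
#' P <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' dag_edges(ominus(P, "b"))
#' @export
ominus <- function(G, v) {
  assert_dag(G)
  v <- unique(as.character(v))
  if (length(v) == 0L) return(G)
  vertex_index(G, v)
  if (length(v) >= G$n) {
    stop_lcadag("cannot suppress every vertex of the DAG", "empty_result")
  }
  em <- dag_edges(G)
  vs <- G$labels
  for (w in v) {
    pa <- em[em[, 2L] == w, 1L]
    ch <- em[em[, 1L] == w, 2L]
    keep <- em[em[, 1L] != w & em[, 2L] != w, , drop = FALSE]
    if (length(pa) > 0L && length(ch) > 0L) {
      new <- cbind(rep(pa, each = length(ch)), rep(ch, times = length(pa)))
      keep <- rbind(keep, new)
    }
    em <- unique(keep)
    vs <- setdiff(vs, w)
  }
  dag(vs, em)
}

#' Simplify a DAG into an LCA-relevant or lca-relevant DAG
#'
#' Both functions suppress unsupported vertices with [ominus()] until every
#' surviving vertex is an LCA (resp. the unique LCA) of some leaf set,
#' while preserving the leaf set (S1), introducing no new vertices (S2) or
#' clusters (S0), preserving ancestry among survivors (S3) and preserving
#' (unique) LCA sets (S4/S5).
#'
#' `make_LCA_relevant()` removes, in one pass evaluated entirely on the
#' input DAG, every vertex `v` with `v` not in `LCA_G(C(v))`. This removal
#' set is the unique minimum set whose suppression yields an LCA-relevant
#' DAG satisfying (S0)-(S5); the output is phylogenetic, keeps the exact
#' cluster system, and stays connected if the input was.
#'
#' `make_lca_relevant()` walks the vertices in the deterministic topological
#' order of the input (ancestors first, lexicographic tie-break) and
#' suppresses the current vertex whenever it is not the unique LCA of its
#' cluster *in the current, already simplified DAG*. The output is
#' lca-relevant, phylogenetic and satisfies (S0)-(S4); in general it depends
#' on the processing order and may lose clusters, but on inputs with the
#' CL or PCC property the removal set coincides with that of
#' `make_LCA_relevant()`, the cluster system is preserved exactly, and the
#' shortcut-free output is isomorphic (via the cluster labelling) to the
#' Hasse diagram of the input's cluster system. Processing ancestors first
#' also means a redundant extra root is removed before the chain vertices
#' it shadows, which keeps the preserved cluster set large.
#'
#' @param G a `dag`.
#' @param verify_lca_sets logical; verify the (S4)/(S5) flags by comparing
#'   LCA sets over all queries of size at most 3 (only attempted when the
#'   DAG has at most `max_verify_leaves` leaves; otherwise the flag is
#'   `NA`).
#' @param max_verify_leaves cap on the leaf count for LCA-set verification.
#' @return An object of class `dag_simplification`: a list with the input
#'   DAG, the `output` DAG, the `removed` vertices in processing order, the
#'   `mode`, and named logical `flags` recording which of (S0)-(S5) were
#'   verified on this instance.
#' @examples
#' G <- fixture_dag("galled_cor710")
#' make_LCA_relevant(G)$removed
#' @export
make_LCA_relevant <- function(G, verify_lca_sets = TRUE, max_verify_leaves = 9L) {
  assert_dag(G)
  W <- character(0)
  for (i in G$topo) {
    v <- G$labels[i]
    if (!(v %in% lca_set(G, G$labels[G$clusters[[i]]]))) W <- c(W, v)
  }
  H <- ominus(G, W)
  new_simplification(G, H, W, "LCA", verify_lca_sets, max_verify_leaves)
}

#' @rdname make_LCA_relevant
#' @export
make_lca_relevant <- function(G, verify_lca_sets = TRUE, max_verify_leaves = 9L) {
  assert_dag(G)
  W <- character(0)
  H <- G
  for (v in G$labels[G$topo]) {
    i <- match(v, H$labels)
    if (is.na(i)) next # cannot happen: each vertex is visited once
    if (!identical(lca_set(H, H$labels[H$clusters[[i]]]), v)) {
      H <- ominus(H, v)
      W <- c(W, v)
    }
  }
  new_simplification(G, H, W, "lca", verify_lca_sets, max_verify_leaves)
}

new_simplification <- function(G, H, W, mode, verify_lca_sets, max_verify_leaves) {
  structure(
    list(
      input = G,
      output = H,
      removed = W,
      mode = mode,
      flags = verify_preservation(G, H, mode, verify_lca_sets, max_verify_leaves),
      shortcut_removal_applied = FALSE
    ),
    class = "dag_simplification"
  )
}

#' @export
print.dag_simplification <- function(x, ...) {
  cat(sprintf("<dag_simplification> mode %s: removed %d of %d vertices\n",
              x$mode, length(x$removed), x$input$n))
  if (length(x$removed) > 0L) {
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  }
  fl <- vapply(x$flags, function(f) if (is.na(f)) "?" else if (f) "ok" else "FAIL", "")
  cat("  ", paste(sprintf("%s:%s", names(fl), fl), collapse = " "), "\n", sep = "")
  invisible(x)
}

# Verify the structural-preservation contract of a simplification.
# S1 leaf set kept; S2 no new vertices; S3 ancestry preserved on survivors;
# S0 no new clusters; S4/S5 (unique) LCA sets preserved, checked over all
# queries with |A| <= 3 when the taxon set is small enough, otherwise NA.
verify_preservation <- function(G, H, mode, verify_lca_sets, max_verify_leaves) {
  s1 <- setequal(leaves(H), leaves(G))
  s2 <- all(H$labels %in% G$labels)
  shared <- intersect(G$labels, H$labels)
  gi <- match(shared, G$labels)
  hi <- match(shared, H$labels)
  s3 <- identical(unname(G$reach[gi, gi, drop = FALSE]),
                  unname(H$reach[hi, hi, drop = FALSE]))
  gkeys <- cluster_keys(G)
  s0 <- all(cluster_keys(H) %in% gkeys)
  s4 <- NA
  s5 <- NA
  if (verify_lca_sets && length(G$leaves) <= max_verify_leaves && s1) {
    X <- leaves(G)
    qs <- small_queries(X, 3L)
    ok5 <- TRUE
    ok4 <- TRUE
    for (A in qs) {
      mg <- lca_set(G, A)
      mh <- lca_set(H, A)
      if (!setequal(mg, mh)) ok5 <- FALSE
      if (length(mg) == 1L && !identical(mh, mg)) ok4 <- FALSE
      if (!ok4 && !ok5) break
    }
    s4 <- ok4
    s5 <- if (mode == "LCA") ok5 else NA
  }
  c(S0 = s0, S1 = s1, S2 = s2, S3 = s3, S4 = s4, S5 = s5)
}

cluster_keys <- function(G) {
  vapply(G$clusters, function(ix) paste(G$labels[ix], collapse = "\r"), "")
}

small_queries <- function(X, kmax) {
  out <- list()
  for (k in seq_len(min(kmax, length(X)))) {
    out <- c(out, utils::combn(X, k, simplify = FALSE))
  }
  out
}

#' Hasse diagram of a cluster system
#'
#' Builds the cover digraph of a set system under inclusion: one vertex per
#' cluster, with an edge from `A` to `B` exactly when `B` is a proper
#' subset of `A` and no cluster lies strictly between them. The Hasse
#' diagram of any set system is shortcut-free and satisfies PCC; for a
#' grounded system it is additionally regular and phylogenetic, and for a
#' clustering system it is a regular network (unique root `X`).
#'
#' With `relabel = TRUE` (requires a grounded system) every singleton
#' vertex `{x}` is renamed to `x`, so the resulting DAG has the input
#' system as its own cluster system. Non-singleton vertices are labelled
#' `"{a,b,...}"` with the sorted member list.
#'
#' @param C a `cluster_system`, or a list of character vectors.
#' @param relabel logical; rename singleton vertices to their element.
#' @return A `dag`; the attribute `"cluster_keys"` maps vertex labels to
#'   cluster contents.
#' @examples
#' H <- hasse(list("x", "y", "z", c("x", "y"), c("x", "y", "z")))
#' is_phylogenetic(H)
#' @export
hasse <- function(C, relabel = TRUE) {
  if (!inherits(C, "cluster_system")) C <- cluster_system(C)
  if (length(C$clusters) == 0L) {
    stop_lcadag("cannot build the Hasse diagram of an empty system", "empty_system")
  }
  if (relabel && !is_grounded(C)) {
    stop_lcadag("relabelling requires a grounded system (all singletons present)",
                "not_grounded")
  }
  cls <- C$clusters
  k <- length(cls)
  lab <- vapply(seq_len(k), function(i) {
    cl <- cls[[i]]
    if (relabel && length(cl) == 1L) cl else paste0("{", paste(cl, collapse = ","), "}")
  }, "")
  if (anyDuplicated(lab)) {
    stop_lcadag("cluster labels collide with taxon labels", "label_collision")
  }
  subset_of <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && length(cls[[i]]) < length(cls[[j]]) &&
          all(cls[[i]] %in% cls[[j]])) {
        subset_of[i, j] <- TRUE # cls[[i]] strictly inside cls[[j]]
      }
    }
  }
  edges <- NULL
  for (j in seq_len(k)) { # parent
    for (i in seq_len(k)) { # child candidate
      if (!subset_of[i, j]) next
      between <- any(subset_of[i, ] & subset_of[, j])
      if (!between) edges <- rbind(edges, c(lab[j], lab[i]))
    }
  }
  H <- dag(lab, edges)
  attr(H, "cluster_keys") <- data.frame(
    label = lab,
    key = vapply(cls, paste, "", collapse = "\r"),
    stringsAsFactors = FALSE
  )
  H
}

#' Simplification maps on DAGs
#'
#' `phi_LCA()` suppresses every non-LCA vertex of `G` (the unique minimum
#' removal set of [make_LCA_relevant()]) and then removes all shortcuts.
#' The image is a shortcut-free LCA-relevant DAG on the same taxa with the
#' same cluster system, and the map satisfies the three simplification
#' axioms: it fixes every shortcut-free LCA-relevant DAG (P1), commutes
#' with leaf relabelling (P2), and commutes with the cluster restriction
#' [cluster_restriction()] (P3). It is idempotent.
#'
#' `phi_lca()` analogously suppresses every vertex that is not the unique
#' LCA of any leaf set, then removes shortcuts. On inputs with the CL (or
#' PCC) property it coincides with `phi_LCA()` and enjoys the same axioms;
#' without CL the axioms are not guaranteed (P3 can fail) and the function
#' proceeds with a warning, since the result can still be informative.
#'
#' @param G a `dag`.
#' @return A `dag`.
#' @export
phi_LCA <- function(G) {
  remove_shortcuts(make_LCA_relevant(G, verify_lca_sets = FALSE)$output)
}

#' @rdname phi_LCA
#' @export
phi_lca <- function(G) {
  assert_dag(G)
  if (!has_cl(G)$holds) {
    warning("phi_lca: input lacks the cluster-lca (CL) property; ",
            "the simplification axioms are not guaranteed", call. = FALSE)
  }
  U <- character(0)
  for (i in G$topo) {
    v <- G$labels[i]
    if (!identical(lca_set(G, G$labels[G$clusters[[i]]]), v)) U <- c(U, v)
  }
  remove_shortcuts(ominus(G, U))
}

#' Cluster restriction of a DAG to a subset of taxa
#'
#' The restriction of `G` to a non-empty leaf subset `Y` is the relabelled
#' Hasse diagram of the traces `C a Y` (over clusters `C` of `G` with a
#' non-empty trace). It makes no structural assumption beyond what the
#' restricted clusters support, and is always a regular DAG. A regular `G`
#' satisfies `cluster_restriction(G, leaves(G))` isomorphic to `G` itself.
#'
#' @param G a `dag`.
#' @param Y non-empty character vector of leaf labels.
#' @return A `dag` on `Y`.
#' @export
cluster_restriction <- function(G, Y) {
  assert_dag(G)
  Y <- unique(as.character(Y))
  if (length(Y) == 0L) stop_lcadag("Y must be non-empty", "empty_restriction")
  if (!all(Y %in% leaves(G))) {
    stop_lcadag("Y must be a subset of the leaf set", "invalid_restriction")
  }
  traces <- lapply(G$clusters, function(ix) intersect(G$labels[ix], Y))
  traces <- traces[lengths(traces) > 0L]
  hasse(cluster_system(traces, ground_set = Y), relabel = TRUE)
}
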