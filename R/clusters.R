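#' Hardwired cluster of a vertex
#'
#' The cluster `C(v)` of a vertex is its set of descendant leaves. Leaves
#' satisfy `C(x) = {x}`; for an inner vertex the cluster is the union of its
#' children's clusters.
#'
#' @param G a `dag`.
#' @param v a vertex label.
#' @return Sorted character vector of leaf labels.
#' @export
dag_cluster <- function(G, v) {
  assert_dag(G)
  G$labels[G$clusters[[vertex_index(G, v)]]]
}

#' Cluster systems
#'
#' A cluster system is a ground set `X` together with a family of non-empty
#' subsets of `X`. The system of a DAG, `cluster_system(G)`, collects the
#' distinct clusters `C(v)` over all vertices; it is always *grounded* (every
#' singleton occurs, the empty set does not). A grounded system containing
#' `X` itself is a *clustering system*; a clustering system without
#' overlapping clusters is a *hierarchy* (the cluster systems of rooted
#' trees).
#'
#' @param x a `dag`, or a list of character vectors (the clusters).
#' @param ground_set optional ground set when `x` is a list; defaults to the
#'   union of the clusters.
#' @param ... unused.
#' @return An object of class `cluster_system` with fields `ground_set` and
#'   `clusters` (a list of sorted character vectors, duplicates removed).
#' @examples
#' G <- fixture_dag("cherry")
#' cluster_system(G)
#' @export
cluster_system <- function(x, ...) UseMethod("cluster_system")

#' @rdname cluster_system
#' @export
cluster_system.dag <- function(x, ...) {
  cls <- lapply(x$clusters, function(ix) x$labels[ix])
  new_cluster_system(cls, ground_set = leaves(x))
}

#' @rdname cluster_system
#' @export
cluster_system.list <- function(x, ground_set = NULL, ...) {
  new_cluster_system(x, ground_set = ground_set)
}

new_cluster_system <- function(clusters, ground_set = NULL) {
  clusters <- lapply(clusters, function(cl) sort(unique(as.character(cl)),
                                                method = "radix"))
  if (any(lengths(clusters) == 0L)) {
    stop_lcadag("the empty set is not a valid cluster", "empty_cluster")
  }
  keys <- vapply(clusters, paste, "", collapse = "\r")
  clusters <- clusters[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  clusters <- clusters[order(keys, method = "radix")]
  members <- unique(unlist(clusters, use.names = FALSE))
  if (is.null(ground_set)) {
    ground_set <- members
  } else {
    ground_set <- as.character(ground_set)
    if (length(setdiff(members, ground_set)) > 0L) {
      stop_lcadag("cluster contains elements outside the ground set",
                  "invalid_cluster")
    }
  }
  structure(
    list(ground_set = sort(unique(ground_set), method = "radix"),
         clusters = clusters),
    class = "cluster_system"
  )
}

#' @export
print.cluster_system <- function(x, ...) {
  cat(sprintf("<cluster_system> %d clusters on %d taxa\n",
              length(x$clusters), length(x$ground_set)))
  shown <- utils::head(x$clusters, 12L)
  for (cl in shown) cat("  {", paste(cl, collapse = ","), "}\n", sep = "")
  if (length(x$clusters) > 12L) cat("  ...\n")
  invisible(x)
}

assert_cluster_system <- function(C) {
  if (!inherits(C, "cluster_system")) {
    stop_lcadag("expected a 'cluster_system' object", "type")
  }
  invisible(C)
}

#' @rdname cluster_system
#' @param C a `cluster_system`.
#' @export
is_grounded <- function(C) {
  assert_cluster_system(C)
  keys <- vapply(C$clusters, paste, "", collapse = "\r")
  all(C$ground_set %in% keys[lengths(C$clusters) == 1L])
}

#' @rdname cluster_system
#' @export
is_clustering_system <- function(C) {
  assert_cluster_system(C)
  is_grounded(C) && any(vapply(C$clusters, function(cl) {
    length(cl) == length(C$ground_set)
  }, NA))
}

#' @rdname cluster_system
#' @export
is_hierarchy <- function(C) {
  assert_cluster_system(C)
  if (!is_clustering_system(C)) return(FALSE)
  k <- length(C$clusters)
  if (k < 2L) return(TRUE)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (sets_overlap(C$clusters[[i]], C$clusters[[j]])) return(FALSE)
    }
  }
  TRUE
}

# Two sets overlap if their intersection is neither empty nor one of them.
sets_overlap <- function(a, b) {
  i <- length(intersect(a, b))
  i > 0L && i < length(a) && i < length(b)
}

#' Shortcut edges and shortcut removal
#'
#' An edge `(u, w)` is a *shortcut* if there is a directed path from `u` to
#' `w` avoiding that edge. Removing all shortcuts yields a uniquely
#' determined DAG `G^-` (the order of deletion does not matter), and the
#' removal preserves the ancestor relation, all clusters, and the
#' path-cluster-comparability verdict.
#'
#' @param G a `dag`.
#' @return `shortcuts()`: a two-column character matrix of shortcut edges;
#'   `remove_shortcuts()`: the shortcut-free `dag` `G^-`.
#' @examples
#' G <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c"), c("a", "c")))
#' shortcuts(G)
#' dag_edges(remove_shortcuts(G))
#' @export
shortcuts <- function(G) {
  assert_dag(G)
  sc <- logical(nrow(G$edges))
  for (k in seq_len(nrow(G$edges))) {
    u <- G$edges[k, 1L]
    w <- G$edges[k, 2L]
    others <- setdiff(G$children[[u]], w)
    sc[k] <- length(others) > 0L && any(G$reach[others, w])
  }
  m <- cbind(G$labels[G$edges[sc, 1L]], G$labels[G$edges[sc, 2L]])
  if (nrow(m) > 0L) m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  colnames(m) <- c("parent", "child")
  m
}

#' @rdname shortcuts
#' @export
remove_shortcuts <- function(G) {
  assert_dag(G)
  sc <- shortcuts(G)
  if (nrow(sc) == 0L) return(G)
  em <- dag_edges(G)
  keep <- !(paste(em[, 1L], em[, 2L], sep = "\r") %in%
              paste(sc[, 1L], sc[, 2L], sep = "\r"))
  dag(G$labels, em[keep, , drop = FALSE])
}
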