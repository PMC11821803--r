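#' Construct a validated, rooted directed acyclic graph
#'
#' A `dag` is a labelled directed acyclic graph. Its leaves `L(G)` are the
#' vertices of out-degree zero (the taxa), its roots `R(G)` the vertices of
#' in-degree zero. DAGs here are more general than phylogenetic networks:
#' they may be disconnected and may have several roots; no super-root is ever
#' added implicitly. Vertex identity is the character label, so equality of
#' DAGs is label-wise.
#'
#' Construction validates the graph (no self-loops, no directed cycles, no
#' dangling edge endpoints) and eagerly computes the derived structure used
#' by every other operation: a deterministic topological order (Kahn's
#' algorithm with lexicographic tie-breaking on labels), the reachability
#' relation, and the hardwired cluster `C(v)` of every vertex, i.e. its set
#' of descendant leaves. `dag` objects are treated as immutable values:
#' structural edits (see [ominus()], [remove_shortcuts()]) return new objects.
#'
#' @param vertices character vector of distinct, non-empty vertex labels.
#' @param edges edges as a two-column character matrix or data frame
#'   (parent, child), or a list of length-2 character vectors; `NULL` or an
#'   empty object for an edgeless DAG. Duplicate ordered pairs are collapsed.
#'
#' @return An object of class `dag`.
#' @examples
#' cherry <- dag(c("w", "x", "y"), rbind(c("w", "x"), c("w", "y")))
#' leaves(cherry)
#' is_ancestor(cherry, "w", "x")
#' @export
dag <- function(vertices, edges = NULL) {
  if (length(vertices) == 0L) {
    stop_lcadag("a DAG needs at least one vertex", "invalid_vertices")
  }
  vertices <- as.character(vertices)
  if (anyNA(vertices) || any(!nzchar(vertices))) {
    stop_lcadag("vertex labels must be non-empty strings", "invalid_vertices")
  }
  if (anyDuplicated(vertices)) {
    stop_lcadag("duplicated vertex label", "invalid_vertices")
  }
  labels <- sort(vertices, method = "radix")
  n <- length(labels)

  em <- normalize_edges(edges)
  if (nrow(em) > 0L) {
    unknown <- setdiff(c(em), labels)
    if (length(unknown) > 0L) {
      stop_lcadag(
        sprintf("unknown vertex in edge list: %s", paste(unknown, collapse = ", ")),
        "unknown_vertex"
      )
    }
    if (any(em[, 1L] == em[, 2L])) {
      stop_lcadag("invalid edge: self-loop", "invalid_edge")
    }
    em <- unique(em)
  }
  eidx <- cbind(match(em[, 1L], labels), match(em[, 2L], labels))

  children <- rep(list(integer(0)), n)
  parents <- rep(list(integer(0)), n)
  if (nrow(eidx) > 0L) {
    ch <- split(eidx[, 2L], eidx[, 1L])
    for (k in names(ch)) children[[as.integer(k)]] <- sort(ch[[k]])
    pa <- split(eidx[, 1L], eidx[, 2L])
    for (k in names(pa)) parents[[as.integer(k)]] <- sort(pa[[k]])
  }

  topo <- kahn_order(n, children, parents)
  if (length(topo) < n) {
    stop_lcadag("not a DAG: directed cycle detected", "not_a_dag")
  }

  # reach[u, v] TRUE iff v is reachable from u (v \preceq u); reflexive.
  reach <- diag(n) > 0
  for (i in rev(topo)) {
    for (ch_i in children[[i]]) reach[i, ] <- reach[i, ] | reach[ch_i, ]
  }

  outdeg <- lengths(children)
  indeg <- lengths(parents)
  leaves_idx <- which(outdeg == 0L)
  roots_idx <- which(indeg == 0L)

  is_leaf <- outdeg == 0L
  clusters <- lapply(seq_len(n), function(i) which(reach[i, ] & is_leaf))

  structure(
    list(
      labels = labels,
      n = n,
      edges = eidx,
      children = children,
      parents = parents,
      topo = topo,
      leaves = leaves_idx,
      roots = roots_idx,
      reach = reach,
      clusters = clusters,
      cache = new.env(parent = emptyenv())
    ),
    class = "dag"
  )
}

normalize_edges <- function(edges) {
  if (is.null(edges) || (is.atomic(edges) && length(edges) == 0L)) {
    return(matrix(character(0), ncol = 2L))
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    if (length(edges) == 0L) return(matrix(character(0), ncol = 2L))
    if (any(lengths(edges) != 2L)) {
      stop_lcadag("each edge must be a (parent, child) pair", "invalid_edge")
    }
    edges <- do.call(rbind, lapply(edges, as.character))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  edges <- matrix(as.character(edges), ncol = 2L)
  if (anyNA(edges)) stop_lcadag("NA in edge list", "invalid_edge")
  edges
}

# Kahn's algorithm; among available in-degree-0 vertices always the
# lexicographically smallest label is taken (labels are sorted, so the
# smallest index is the smallest label).
kahn_order <- function(n, children, parents) {
  indeg <- lengths(parents)
  avail <- which(indeg == 0L)
  topo <- integer(0)
  while (length(avail) > 0L) {
    v <- min(avail)
    avail <- avail[avail != v]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
  }
  topo
}

stop_lcadag <- function(msg, subclass, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("lcadag_", subclass), "lcadag_error"),
                      call = call))
}

is_dag_object <- function(x) inherits(x, "dag")

assert_dag <- function(G) {
  if (!is_dag_object(G)) stop_lcadag("expected a 'dag' object", "type")
  invisible(G)
}

vertex_index <- function(G, v) {
  i <- match(v, G$labels)
  if (anyNA(i)) {
    stop_lcadag(sprintf("unknown vertex: %s", paste(v[is.na(i)], collapse = ", ")),
                "unknown_vertex")
  }
  i
}

#' @rdname dag-accessors
#' @export
dag_vertices <- function(G) {
  assert_dag(G)
  G$labels
}

#' Accessors for `dag` objects
#'
#' `dag_vertices()` and `dag_edges()` return the vertex labels and the edge
#' list; `leaves()` and `roots()` return the out-degree-0 and in-degree-0
#' vertices; `dag_children()` and `dag_parents()` the direct successors and
#' predecessors of a vertex. All outputs are sorted for reproducibility.
#'
#' @param G a `dag`.
#' @param v a vertex label.
#' @return Character vectors (a two-column character matrix for
#'   `dag_edges()`).
#' @name dag-accessors
#' @export
dag_edges <- function(G) {
  assert_dag(G)
  m <- cbind(G$labels[G$edges[, 1L]], G$labels[G$edges[, 2L]])
  if (nrow(m) > 0L) m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  colnames(m) <- c("parent", "child")
  m
}

#' @rdname dag-accessors
#' @export
leaves <- function(G) {
  assert_dag(G)
  G$labels[G$leaves]
}

#' @rdname dag-accessors
#' @export
roots <- function(G) {
  assert_dag(G)
  G$labels[G$roots]
}

#' @rdname dag-accessors
#' @export
dag_children <- function(G, v) {
  assert_dag(G)
  G$labels[G$children[[vertex_index(G, v)]]]
}

#' @rdname dag-accessors
#' @export
dag_parents <- function(G, v) {
  assert_dag(G)
  G$labels[G$parents[[vertex_index(G, v)]]]
}

#' Ancestor relation of a DAG
#'
#' Tests whether `v` is a descendant of `u`, i.e. whether there is a directed
#' path (possibly of length zero) from `u` to `v`. The relation is reflexive
#' and transitive; two vertices with no connecting path in either direction
#' are incomparable.
#'
#' @param G a `dag`.
#' @param u,v vertex labels.
#' @return `TRUE` iff `v` is reachable from `u`.
#' @export
is_ancestor <- function(G, u, v) {
  assert_dag(G)
  G$reach[vertex_index(G, u), vertex_index(G, v)]
}

#' @export
print.dag <- function(x, ...) {
  cat(sprintf("<dag> %d vertices, %d edges; %d leaves, %d roots\n",
              x$n, nrow(x$edges), length(x$leaves), length(x$roots)))
  cat("  leaves:", paste(utils::head(x$labels[x$leaves], 10L), collapse = ", "),
      if (length(x$leaves) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Label-wise equality of DAGs
#'
#' Two DAGs are equal when they have identical vertex label sets and
#' identical edge sets. Isomorphism up to relabelling is a different notion,
#' see [dag_isomorphic()].
#'
#' @param G,H `dag` objects.
#' @return `TRUE` or `FALSE`.
#' @export
dag_equal <- function(G, H) {
  assert_dag(G)
  assert_dag(H)
  identical(G$labels, H$labels) && identical(dag_edges(G), dag_edges(H))
}

#' Rebuild a DAG with a new edge set over the same (or fewer) vertices
#' @noRd
rebuild_dag <- function(labels, edge_labels) {
  dag(labels, edge_labels)
}

#' Is a DAG phylogenetic?
#'
#' A directed graph is phylogenetic if it has no vertex with out-degree 1 and
#' in-degree at most 1. Such vertices cannot be supported by any data at the
#' leaves, which is why inferred evolutionary DAGs are required not to
#' contain them.
#'
#' @param G a `dag`.
#' @return `TRUE` or `FALSE`.
#' @export
is_phylogenetic <- function(G) {
  assert_dag(G)
  outdeg <- lengths(G$children)
  indeg <- lengths(G$parents)
  !any(outdeg == 1L & indeg <= 1L)
}

#' Relabel the leaves of a DAG by a permutation
#'
#' Applies a permutation of the taxa to a DAG, leaving inner vertex labels
#' untouched (inner labels are renamed only if the permutation would collide
#' with them, which is an error). Used to state and test equivariance of
#' simplification maps under leaf relabelling.
#'
#' @param G a `dag`.
#' @param perm named character vector mapping old leaf labels to new ones; a
#'   bijection on `leaves(G)`.
#' @return A `dag` with permuted leaf labels.
#' @export
permute_leaves <- function(G, perm) {
  assert_dag(G)
  lv <- leaves(G)
  if (!setequal(names(perm), lv) || !setequal(unname(perm), lv)) {
    stop_lcadag("perm must be a bijection on the leaf set", "invalid_permutation")
  }
  map <- G$labels
  names(map) <- G$labels
  map[names(perm)] <- unname(perm)
  if (anyDuplicated(map)) {
    stop_lcadag("leaf permutation collides with inner vertex labels",
                "invalid_permutation")
  }
  em <- dag_edges(G)
  dag(unname(map[G$labels]),
      cbind(unname(map[em[, 1L]]), unname(map[em[, 2L]])))
}
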