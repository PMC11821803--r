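#' Least common ancestors of a leaf set
#'
#' `lca_set()` computes the set `LCA_G(A)` of all least common ancestors of
#' a non-empty set of leaves `A`: the reachability-minimal vertices that are
#' ancestors of every element of `A`. In a general DAG this set may be empty
#' (two leaves can lack a common ancestor altogether) or contain several
#' pairwise incomparable vertices; in a rooted network it is always
#' non-empty.
#'
#' The implementation is the linear-time topological sweep: processing
#' vertices against a topological order, it maintains for every vertex `v`
#' the residue `A \ C(v)` (for a leaf this is `A \ {v}`, for an inner vertex
#' the intersection of the residues of its children). A vertex belongs to
#' `LCA_G(A)` exactly when its own residue is empty while the residue of
#' every child is non-empty. The sweep runs in `O((|V| + |E|) |A|)` time.
#'
#' `lca()` returns the unique least common ancestor `lca_G(A)` when
#' `LCA_G(A)` is a singleton, and `NA_character_` otherwise ("undefined" is
#' a legitimate answer, not an error).
#'
#' `lca_bruteforce()` is a deliberately definition-faithful oracle: it
#' intersects the ancestor sets of the elements of `A` and keeps the minimal
#' elements. It is retained as an independent cross-check for the sweep and
#' used throughout the test suite.
#'
#' @param G a `dag`.
#' @param A character vector of leaf labels, non-empty.
#' @return `lca_set()` and `lca_bruteforce()`: sorted character vector of
#'   vertex labels (possibly empty). `lca()`: a single label or
#'   `NA_character_`.
#' @examples
#' G <- fixture_dag("cherry")
#' lca_set(G, c("x", "y"))
#' lca(G, c("x", "y"))
#' @export
lca_set <- function(G, A) {
  aidx <- check_query(G, A)
  if (length(aidx) == 1L) return(G$labels[aidx])
  res <- vector("list", G$n)
  members <- integer(0)
  for (i in rev(G$topo)) {
    ch <- G$children[[i]]
    if (length(ch) == 0L) {
      res[[i]] <- setdiff(aidx, i)
    } else {
      r <- res[[ch[1L]]]
      for (j in ch[-1L]) {
        if (length(r) == 0L) break
        r <- intersect(r, res[[j]])
      }
      res[[i]] <- r
    }
    if (length(res[[i]]) == 0L &&
        (length(ch) == 0L || all(lengths(res[ch]) > 0L))) {
      members <- c(members, i)
    }
  }
  G$labels[sort(members)]
}

check_query <- function(G, A) {
  assert_dag(G)
  if (length(A) == 0L) stop_lcadag("empty query: A must be non-empty", "empty_query")
  A <- unique(as.character(A))
  aidx <- match(A, G$labels)
  if (anyNA(aidx)) {
    stop_lcadag(sprintf("unknown vertex: %s", paste(A[is.na(aidx)], collapse = ", ")),
                "unknown_vertex")
  }
  if (!all(aidx %in% G$leaves)) {
    bad <- A[!(aidx %in% G$leaves)]
    stop_lcadag(sprintf("non-leaf in query: %s", paste(bad, collapse = ", ")),
                "non_leaf_query")
  }
  sort(aidx)
}

#' @rdname lca_set
#' @export
lca <- function(G, A) {
  m <- lca_set(G, A)
  if (length(m) == 1L) m else NA_character_
}

#' @rdname lca_set
#' @export
lca_bruteforce <- function(G, A) {
  aidx <- check_query(G, A)
  # common ancestors: vertices reaching every element of A
  if (length(aidx) == 1L) {
    ca <- which(G$reach[, aidx])
  } else {
    ca <- which(rowSums(G$reach[, aidx, drop = FALSE]) == length(aidx))
  }
  if (length(ca) == 0L) return(character(0))
  minimal <- vapply(ca, function(u) {
    !any(G$reach[u, setdiff(ca, u)])
  }, NA)
  G$labels[sort(ca[minimal])]
}

#' Is a vertex an LCA (or unique LCA) of some leaf set?
#'
#' A vertex `v` is a *k-LCA vertex* if `v` belongs to `LCA_G(A)` for some
#' leaf set `A` of size `k`, and a *k-lca vertex* if it is the unique LCA of
#' such a set. `v` is an LCA vertex for *some* `k` if and only if
#' `v %in% lca_set(G, C(v))`; it is a unique-LCA vertex for some `k` iff
#' `v == lca(G, C(v))`. Equivalently, `v` fails to be an LCA vertex exactly
#' when some child has the same cluster as `v`.
#'
#' @param G a `dag`.
#' @param v a vertex label.
#' @return `TRUE` or `FALSE`.
#' @export
is_LCA_vertex <- function(G, v) {
  assert_dag(G)
  vi <- vertex_index(G, v)
  cl <- G$labels[G$clusters[[vi]]]
  v %in% lca_set(G, cl)
}

#' @rdname is_LCA_vertex
#' @export
is_lca_vertex <- function(G, v) {
  assert_dag(G)
  vi <- vertex_index(G, v)
  cl <- G$labels[G$clusters[[vi]]]
  identical(lca_set(G, cl), unname(v))
}

#' Is a vertex a k-LCA (or k-lca) vertex for a given k?
#'
#' Tests whether `v` is an LCA (resp. unique LCA) of some leaf set of size
#' exactly `k`. For `k = 1` this holds precisely for leaves. No vertex can
#' be a k-LCA vertex for `k > |C(v)|`, and the admissible sizes always form
#' an interval ending at `|C(v)|` (see [lca_size_interval()]).
#'
#' The general problem is NP-complete, so the explicit-`k` test enumerates
#' size-`k` subsets of `C(v)` under a configurable work bound and raises a
#' typed error (`lcadag_work_bound`) when the search space exceeds it. For
#' DAGs without three pairwise overlapping clusters (the N3O class, which
#' contains trees and galled trees) a polynomial fast path applies: for
#' `k >= 2`, `v` is a k-LCA vertex iff `|C(v)| >= 2`, no child shares `v`'s
#' cluster and `k <= |C(v)|`; it is a k-lca vertex iff `v == lca(G, C(v))`
#' and `2 <= k <= |C(v)|`. The N3O verdict is detected once per DAG and
#' cached.
#'
#' @param G a `dag`.
#' @param v a vertex label.
#' @param k integer, `1 <= k <= |L(G)|`.
#' @param max_subsets work bound for the exhaustive (non-N3O) search; the
#'   number of candidate subsets that may be enumerated.
#' @return `TRUE` or `FALSE`.
#' @export
is_k_LCA <- function(G, v, k, max_subsets = 1e6) {
  k_vertex_test(G, v, k, unique = FALSE, max_subsets = max_subsets)
}

#' @rdname is_k_LCA
#' @export
is_k_lca <- function(G, v, k, max_subsets = 1e6) {
  k_vertex_test(G, v, k, unique = TRUE, max_subsets = max_subsets)
}

k_vertex_test <- function(G, v, k, unique, max_subsets) {
  assert_dag(G)
  vi <- vertex_index(G, v)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(G$leaves)) {
    stop_lcadag(sprintf("k out of range: %s", k), "invalid_k")
  }
  csize <- length(G$clusters[[vi]])
  if (k == 1L) return(vi %in% G$leaves)
  if (k > csize) return(FALSE)
  if (dag_is_n3o(G)) {
    if (unique) {
      return(is_lca_vertex(G, v))
    }
    no_equal_child <- !any(vapply(G$children[[vi]], function(u) {
      identical(G$clusters[[u]], G$clusters[[vi]])
    }, NA))
    return(csize >= 2L && no_equal_child)
  }
  n_cand <- choose(csize, k)
  if (n_cand > max_subsets) {
    stop_lcadag(
      sprintf("intractable: work bound exceeded (%.0f candidate subsets > %g)",
              n_cand, max_subsets),
      "work_bound"
    )
  }
  cl <- G$labels[G$clusters[[vi]]]
  found <- FALSE
  utils::combn(cl, k, FUN = function(A) {
    if (!found) {
      m <- lca_set(G, A)
      hit <- if (unique) identical(m, unname(v)) else v %in% m
      if (hit) found <<- TRUE
    }
    NULL
  }, simplify = FALSE)
  found
}

#' Admissible query sizes of a vertex
#'
#' The sizes `k` for which a vertex is a k-LCA (mode `"LCA"`) or k-lca
#' (mode `"lca"`) vertex form an interval whose right endpoint is `|C(v)|`.
#' This returns that interval as `c(k_min, |C(v)|)`, or `integer(0)` when
#' the vertex is not an LCA (unique LCA) vertex for any size. On N3O DAGs
#' the left endpoint of an inner vertex's interval is always 2; otherwise it
#' is found by ascending search under the work bound of [is_k_LCA()].
#'
#' @inheritParams is_k_LCA
#' @param mode `"LCA"` or `"lca"`.
#' @return Integer vector `c(k_min, k_max)` or `integer(0)`.
#' @export
lca_size_interval <- function(G, v, mode = c("LCA", "lca"), max_subsets = 1e6) {
  mode <- match.arg(mode)
  assert_dag(G)
  vi <- vertex_index(G, v)
  some <- if (mode == "LCA") is_LCA_vertex(G, v) else is_lca_vertex(G, v)
  if (!some) return(integer(0))
  if (vi %in% G$leaves) return(c(1L, 1L))
  csize <- length(G$clusters[[vi]])
  if (dag_is_n3o(G)) return(c(2L, csize))
  test <- if (mode == "LCA") is_k_LCA else is_k_lca
  for (k in 2:csize) {
    if (test(G, v, k, max_subsets = max_subsets)) return(c(k, csize))
  }
  integer(0) # unreachable: `some` guarantees k = |C(v)| is admissible
}
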