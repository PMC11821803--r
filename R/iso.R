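#' DAG isomorphism utilities
#'
#' `dag_cluster_isomorphic()` tests isomorphism through the canonical
#' cluster labelling: it applies when both DAGs have pairwise distinct
#' clusters (always true for lca-relevant DAGs), and holds when the two
#' cluster systems coincide and the edge sets correspond under the map
#' `v -> C(v)`. This is the comparison used for Hasse-diagram identities.
#'
#' `dag_isomorphic()` is a small-instance backtracking check intended for
#' tests. With `fix_leaves = TRUE` (the default, matching the phylogenetic
#' convention) leaves must map to the identically labelled leaves; inner
#' vertices may map freely subject to degree-compatibility.
#'
#' @param G,H `dag` objects.
#' @param fix_leaves logical; require the identity on leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
dag_cluster_isomorphic <- function(G, H) {
  assert_dag(G)
  assert_dag(H)
  gk <- cluster_keys(G)
  hk <- cluster_keys(H)
  if (anyDuplicated(gk) || anyDuplicated(hk)) {
    stop_lcadag("cluster labelling requires pairwise distinct clusters",
                "duplicate_clusters")
  }
  if (G$n != H$n || !setequal(gk, hk)) return(FALSE)
  ge <- paste(gk[G$edges[, 1L]], gk[G$edges[, 2L]], sep = "\n")
  he <- paste(hk[H$edges[, 1L]], hk[H$edges[, 2L]], sep = "\n")
  setequal(ge, he)
}

#' @rdname dag_cluster_isomorphic
#' @export
dag_isomorphic <- function(G, H, fix_leaves = TRUE) {
  assert_dag(G)
  assert_dag(H)
  if (G$n != H$n || nrow(G$edges) != nrow(H$edges)) return(FALSE)
  sig <- function(D) sort(paste(lengths(D$parents), lengths(D$children)))
  if (!identical(sig(G), sig(H))) return(FALSE)
  if (fix_leaves && !setequal(leaves(G), leaves(H))) return(FALSE)

  n <- G$n
  gdeg <- paste(lengths(G$parents), lengths(G$children))
  hdeg <- paste(lengths(H$parents), lengths(H$children))
  cand <- lapply(seq_len(n), function(i) {
    js <- which(hdeg == gdeg[i] &
                  (seq_len(H$n) %in% H$leaves) == (i %in% G$leaves))
    if (fix_leaves && i %in% G$leaves) {
      js <- js[H$labels[js] == G$labels[i]]
    }
    js
  })
  order_v <- order(lengths(cand))
  map <- integer(n) # 0 = unassigned
  used <- logical(n)

  consistent <- function(i, j) {
    for (p in G$parents[[i]]) {
      if (map[p] != 0L && !(map[p] %in% H$parents[[j]])) return(FALSE)
    }
    for (ch in G$children[[i]]) {
      if (map[ch] != 0L && !(map[ch] %in% H$children[[j]])) return(FALSE)
    }
    # reverse direction: assigned G-neighbours were checked; also ensure no
    # spurious H-edge between j and images of assigned non-neighbours
    for (p in H$parents[[j]]) {
      ip <- match(p, map)
      if (!is.na(ip) && !(ip %in% G$parents[[i]])) return(FALSE)
    }
    for (ch in H$children[[j]]) {
      ic <- match(ch, map)
      if (!is.na(ic) && !(ic %in% G$children[[i]])) return(FALSE)
    }
    TRUE
  }

  bt <- function(pos) {
    if (pos > n) return(TRUE)
    i <- order_v[pos]
    for (j in cand[[i]]) {
      if (used[j] || !consistent(i, j)) next
      map[i] <<- j
      used[j] <<- TRUE
      if (bt(pos + 1L)) return(TRUE)
      map[i] <<- 0L
      used[j] <<- FALSE
    }
    FALSE
  }
  bt(1L)
}
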