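#' Read and write DAGs
#'
#' Two plain-text interchange formats are supported. The JSON format (the
#' primary one; DAGs are not trees, so Newick is unsuitable) is an object
#' with a `format` tag, a sorted `vertices` array and a sorted `edges`
#' array of `[parent, child]` pairs; serialization is canonical, so two
#' equal DAGs produce byte-identical files. The TSV format has one
#' `parent<TAB>child` line per edge; vertices without incident edges are
#' declared on single-column lines. Reading validates through [dag()], so
#' malformed input (cycles, self-loops, unknown endpoints) fails with the
#' same typed errors, prefixed with the file path.
#'
#' @param G a `dag`.
#' @param path file path.
#' @param format `"json"` or `"tsv"`; for reading, inferred from the file
#'   extension when missing.
#' @param name optional name stored in the JSON metadata.
#' @return `read_dag()`: a `dag`. `write_dag()`: `path`, invisibly.
#' @export
write_dag <- function(G, path, format = c("json", "tsv"), name = NULL) {
  assert_dag(G)
  format <- match.arg(format)
  em <- dag_edges(G)
  if (format == "json") {
    doc <- list(format = "lcadag/1", vertices = G$labels,
                edges = unname(apply(em, 1L, function(r) as.list(unname(r)),
                                     simplify = FALSE)))
    if (!is.null(name)) doc$name <- name
    json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
    writeLines(json, path, useBytes = TRUE)
  } else {
    isolated <- setdiff(G$labels, unique(c(em)))
    lines <- c(isolated, sprintf("%s\t%s", em[, 1L], em[, 2L]))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_dag
#' @export
read_dag <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  format <- match.arg(format, c("json", "tsv"))
  if (format == "json") {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                    error = function(e) {
                      stop_lcadag(sprintf("%s: malformed JSON (%s)",
                                          path, conditionMessage(e)), "parse")
                    })
    if (is.null(doc$vertices)) {
      stop_lcadag(sprintf("%s: missing 'vertices'", path), "parse")
    }
    edges <- doc$edges
    if (is.data.frame(edges)) {
      edges <- as.matrix(edges)
    } else if (is.list(edges)) {
      edges <- do.call(rbind, lapply(edges, unlist))
    }
    with_file_context(path, dag(doc$vertices, edges))
  } else {
    lines <- readLines(path, warn = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf > 2L | nf == 0L)) {
      bad <- which(nf > 2L | nf == 0L)[1L]
      stop_lcadag(sprintf("%s: malformed line %d: '%s'", path, bad, lines[bad]),
                  "parse")
    }
    isolated <- unlist(fields[nf == 1L])
    em <- do.call(rbind, fields[nf == 2L])
    vertices <- unique(c(isolated, c(em)))
    with_file_context(path, dag(vertices, em))
  }
}

with_file_context <- function(path, expr) {
  tryCatch(expr, lcadag_error = function(e) {
    stop(errorCondition(sprintf("%s: %s", path, conditionMessage(e)),
                        class = class(e)))
  })
}

#' Read and write cluster systems
#'
#' Clusters are stored one per line as comma-separated, sorted leaf
#' labels (labels must not contain commas). Duplicate lines are collapsed
#' with a warning; empty lines are an error.
#'
#' @param C a `cluster_system`.
#' @param path file path.
#' @return `read_clusters()`: a `cluster_system`. `write_clusters()`:
#'   `path`, invisibly.
#' @export
write_clusters <- function(C, path) {
  assert_cluster_system(C)
  lines <- vapply(C$clusters, paste, "", collapse = ",")
  writeLines(sort(lines, method = "radix"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(!nzchar(trimws(lines)))) {
    bad <- which(!nzchar(trimws(lines)))[1L]
    stop_lcadag(sprintf("%s: empty cluster on line %d", path, bad), "parse")
  }
  if (anyDuplicated(lines)) {
    warning(sprintf("%s: duplicate cluster lines collapsed", path), call. = FALSE)
    lines <- unique(lines)
  }
  cls <- strsplit(lines, ",", fixed = TRUE)
  if (any(vapply(cls, function(cl) any(!nzchar(cl)), NA))) {
    stop_lcadag(sprintf("%s: empty label in a cluster line", path), "parse")
  }
  cluster_system(cls)
}
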