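#' Binary undirected graph
#'
#' Lightweight container for the unweighted, undirected graphs obtained by
#' thresholding a connectivity matrix (or built directly as fixtures). Edges
#' are stored as a two-column integer matrix with the smaller endpoint first;
#' self-loops and duplicate edges are rejected.
#'
#' @param edges two-column integer matrix (or vector coercible to one) of
#'   node-pair endpoints, 1-based.
#' @param n_nodes number of nodes in the graph.
#' @param threshold_r the correlation threshold that produced the graph, or
#'   `NA` for fixtures.
#' @param labels optional character vector of node labels (length `n_nodes`).
#' @return an object of class `binary_graph` with fields `n_nodes`, `edges`,
#'   `threshold_r` and `labels`.
#' @export
binary_graph <- function(edges, n_nodes, threshold_r = NA_real_,
                         labels = NULL) {
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop("graph must have at least one node")
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n_nodes)) {
      stop("edge endpoints outside node range 1..", n_nodes)
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    key <- (edges[, 1L] - 1) * n_nodes + edges[, 2L]
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  if (is.null(labels)) labels <- paste0("n", seq_len(n_nodes))
  if (length(labels) != n_nodes) stop("labels must have length n_nodes")
  structure(
    list(n_nodes = n_nodes, edges = edges,
         threshold_r = as.numeric(threshold_r),
         labels = as.character(labels)),
    class = "binary_graph"
  )
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("binary_graph: %d nodes, %d edges", x$n_nodes, n_edges(x)))
  if (!is.na(x$threshold_r)) cat(sprintf(" (threshold r = %g)", x$threshold_r))
  cat("\n")
  invisible(x)
}

#' Number of edges of a binary graph
#' @param g a `binary_graph`.
#' @return integer edge count.
#' @export
n_edges <- function(g) nrow(g$edges)

#' Dense adjacency matrix of a binary graph
#' @param g a `binary_graph`.
#' @return symmetric 0/1 numeric matrix with zero diagonal.
#' @export
adjacency_matrix <- function(g) {
  A <- matrix(0, g$n_nodes, g$n_nodes,
              dimnames = list(g$labels, g$labels))
  if (n_edges(g) > 0L) {
    A[g$edges] <- 1
    A[g$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

#' Build a binary graph from an adjacency matrix
#' @param A symmetric square matrix; entries > 0 become edges, diagonal
#'   ignored.
#' @param threshold_r threshold to record on the graph.
#' @param labels optional node labels (defaults to rownames of `A`).
#' @return a `binary_graph`.
#' @export
graph_from_adjacency <- function(A, threshold_r = NA_real_, labels = NULL) {
  if (!isSymmetric(unname(A > 0))) stop("adjacency matrix must be symmetric")
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (is.null(labels)) labels <- rownames(A)
  binary_graph(idx, nrow(A), threshold_r = threshold_r, labels = labels)
}

# adjacency list (list of integer neighbour vectors), used by the
# traversal-based algorithms
neighbour_list <- function(g) {
  adj <- vector("list", g$n_nodes)
  for (i in seq_len(g$n_nodes)) adj[[i]] <- integer(0)
  e <- g$edges
  if (nrow(e) > 0L) {
    for (k in seq_len(nrow(e))) {
      adj[[e[k, 1L]]] <- c(adj[[e[k, 1L]]], e[k, 2L])
      adj[[e[k, 2L]]] <- c(adj[[e[k, 2L]]], e[k, 1L])
    }
  }
  adj
}

#' Write a binary graph as a two-column edge list
#'
#' @param g a `binary_graph`.
#' @param path output file path (TSV, columns `from`, `to` using node labels).
#' @return the path, invisibly.
#' @export
write_edge_list <- function(g, path) {
  df <- data.frame(from = g$labels[g$edges[, 1L]],
                   to = g$labels[g$edges[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a binary graph in GraphML format
#'
#' Uses igraph's GraphML writer when igraph is installed; otherwise emits a
#' minimal conforming GraphML document directly.
#'
#' @param g a `binary_graph`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_graphml <- function(g, path) {
  if (requireNamespace("igraph", quietly = TRUE)) {
    ig <- igraph::graph_from_edgelist(
      matrix(g$labels[g$edges], ncol = 2L), directed = FALSE)
    iso <- setdiff(g$labels, igraph::V(ig)$name)
    if (length(iso)) ig <- igraph::add_vertices(ig, length(iso), name = iso)
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <graph id="G" edgedefault="undirected">'), con)
    writeLines(sprintf('    <node id="%s"/>', g$labels), con)
    if (n_edges(g) > 0L) {
      writeLines(sprintf('    <edge source="%s" target="%s"/>',
                         g$labels[g$edges[, 1L]],
                         g$labels[g$edges[, 2L]]), con)
    }
    writeLines(c("  </graph>", "</graphml>"), con)
  }
  invisible(path)
}
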