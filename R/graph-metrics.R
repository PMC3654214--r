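#' Node degrees
#'
#' Degree of node i is the number of edges attaching it to its neighbours;
#' the graph degree is the mean over all nodes.
#'
#' @param g a `binary_graph`.
#' @return list with `per_node` (named integer vector) and `mean`.
#' @export
degrees <- function(g) {
  d <- integer(g$n_nodes)
  if (n_edges(g) > 0L) {
    tb <- tabulate(as.vector(g$edges), nbins = g$n_nodes)
    d <- tb
  }
  names(d) <- g$labels
  list(per_node = d, mean = mean(d))
}

#' All-pairs shortest path lengths
#'
#' Breadth-first (unweighted) shortest-path edge counts between every node
#' pair. Unreachable pairs are flagged as `Inf` rather than given a finite
#' length; downstream summaries treat them by their own documented
#' conventions.
#'
#' @param g a `binary_graph`.
#' @return symmetric numeric matrix of distances, zero diagonal, `Inf` for
#'   unreachable pairs.
#' @export
shortest_path_lengths <- function(g) {
  n <- g$n_nodes
  A <- adjacency_matrix(g)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(D) <- 0
  # level-synchronous BFS from all sources simultaneously via boolean
  # matrix products: frontier at step k holds pairs first reached at
  # distance k
  frontier <- A > 0
  known <- frontier | diag(n) > 0
  D[frontier] <- 1
  k <- 1L
  while (any(frontier)) {
    nxt <- ((frontier %*% A) > 0) & !known
    if (!any(nxt)) break
    k <- k + 1L
    D[nxt] <- k
    known <- known | nxt
    frontier <- nxt
  }
  D
}

#' Characteristic path length
#'
#' Mean shortest path length L_i of node i is the average of its finite
#' distances to other nodes; the characteristic path length L of the graph
#' is the mean of L_i over nodes with at least one reachable partner.
#' Unreachable pairs are excluded from the averages (so L stays defined on
#' fragmented graphs); a graph with no edges has no defined L and returns
#' `NA` with a flag.
#'
#' @param g a `binary_graph`.
#' @param distances optional precomputed matrix from
#'   [shortest_path_lengths()].
#' @return list with `per_node` (L_i, `NA` for isolated nodes), `mean` (L)
#'   and `defined` (FALSE when no node pair is connected).
#' @export
characteristic_path_length <- function(g, distances = NULL) {
  D <- if (is.null(distances)) shortest_path_lengths(g) else distances
  diag(D) <- NA
  finite <- is.finite(D)
  li <- vapply(seq_len(nrow(D)), function(i) {
    di <- D[i, ][finite[i, ]]
    if (length(di) == 0L) NA_real_ else mean(di)
  }, numeric(1))
  names(li) <- g$labels
  defined <- any(!is.na(li))
  list(per_node = li,
       mean = if (defined) mean(li, na.rm = TRUE) else NA_real_,
       defined = defined)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest path length, with
#' unreachable pairs contributing zero.
#'
#' @param g a `binary_graph`.
#' @param distances optional precomputed distance matrix.
#' @return numeric scalar in \[0, 1\].
#' @export
global_efficiency <- function(g, distances = NULL) {
  n <- g$n_nodes
  if (n < 2L) return(0)
  D <- if (is.null(distances)) shortest_path_lengths(g) else distances
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Clustering coefficients
#'
#' C_i = R_i / (D_i (D_i - 1) / 2) where R_i counts the adjacent pairs
#' among the neighbours of i (the closed triangles through i). Nodes with
#' fewer than two neighbours have C_i = 0 by convention (the denominator
#' vanishes).
#'
#' @param g a `binary_graph`.
#' @return list with `per_node` and `mean`.
#' @export
clustering_coefficients <- function(g) {
  A <- adjacency_matrix(g)
  deg <- rowSums(A)
  # diagonal of A^3 counts closed 3-walks = 2 * triangles through the node
  tri <- diag(A %*% A %*% A) / 2
  ci <- ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
  names(ci) <- g$labels
  list(per_node = ci, mean = mean(ci))
}

#' Local efficiency
#'
#' For each node i, the global efficiency of the subgraph induced by the
#' neighbours of i: the mean over ordered neighbour pairs of the inverse
#' within-subgraph shortest path length. Nodes with fewer than two
#' neighbours score 0.
#'
#' @param g a `binary_graph`.
#' @return list with `per_node` and `mean`.
#' @export
local_efficiency <- function(g) {
  A <- adjacency_matrix(g)
  n <- g$n_nodes
  ei <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    v <- length(nb)
    if (v < 2L) next
    sub <- graph_from_adjacency(A[nb, nb, drop = FALSE])
    ei[i] <- global_efficiency(sub)
  }
  names(ei) <- g$labels
  list(per_node = ei, mean = mean(ei))
}

#' Betweenness centrality
#'
#' Normalized betweenness of node i: the sum over ordered source-target
#' pairs (f, j), f != j, both distinct from i, of the fraction of shortest
#' f-j paths passing through i, scaled by 1/((N-1)(N-2)). Pairs with no
#' connecting path contribute zero. Computed by Brandes' pair-dependency
#' accumulation, which is exact and tractable at brain-network size.
#'
#' @param g a `binary_graph` with at least 3 nodes.
#' @return named numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(g) {
  n <- g$n_nodes
  if (n < 3L) stop("betweenness centrality needs at least 3 nodes")
  adj <- neighbour_list(g)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    order <- integer(0)
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      order <- c(order, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L; queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(order)) {
      for (p in preds[[v]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  # each accumulation pass contributes ordered (source, target) pairs
  bc <- bc / ((n - 1) * (n - 2))
  names(bc) <- g$labels
  bc
}

#' Identify hub nodes
#'
#' Hubs are the top-ranked nodes by degree or by betweenness centrality.
#' Ties are broken deterministically by node label order.
#'
#' @param g a `binary_graph`.
#' @param method `"degree"` or `"betweenness"`.
#' @param k how many hubs to return (1 <= k <= number of nodes).
#' @return character vector of `k` node labels, highest-ranked first.
#' @export
identify_hubs <- function(g, method = c("degree", "betweenness"), k = 1L) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 1L || k > g$n_nodes) stop("k must be between 1 and n_nodes")
  score <- switch(method,
    degree = degrees(g)$per_node,
    betweenness = betweenness_centrality(g))
  ord <- order(-score, seq_along(score))
  g$labels[ord[seq_len(k)]]
}

#' Degree distribution histogram
#'
#' @param g a `binary_graph`.
#' @param bin_edges increasing numeric vector of bin boundaries covering all
#'   observed degrees; bins are left-closed (`[a, b)`, last bin closed).
#' @return named integer vector of counts, one per bin; counts sum to the
#'   number of nodes.
#' @export
degree_distribution <- function(g, bin_edges = NULL) {
  d <- degrees(g)$per_node
  if (is.null(bin_edges)) bin_edges <- seq(-0.5, max(d) + 0.5, by = 1)
  if (min(d) < bin_edges[1L] || max(d) > bin_edges[length(bin_edges)]) {
    stop("observed degrees fall outside the supplied bins")
  }
  h <- graphics::hist(d, breaks = bin_edges, plot = FALSE, right = FALSE)
  counts <- h$counts
  # right = FALSE leaves a degree equal to the last edge in no bin; close it
  counts[length(counts)] <- counts[length(counts)] +
    sum(d == bin_edges[length(bin_edges)])
  names(counts) <- sprintf("[%g,%g)", bin_edges[-length(bin_edges)],
                           bin_edges[-1L])
  counts
}

#' Compute every node-level and graph-level measure for one graph
#'
#' Convenience driver producing the long-format metric table used by the
#' session comparison stage: one row per (node, measure) and per graph-level
#' measure. Strength columns are included when the weighted connectivity
#' matrix is supplied (strength is defined on the complete weighted graph,
#' not the thresholded one).
#'
#' @param g a `binary_graph`.
#' @param cm optional `connectivity_matrix` for the strength measure.
#' @param subject,session identifiers copied into the table.
#' @param measures which measure families to compute (any of `"degree"`,
#'   `"path_length"`, `"clustering"`, `"local_efficiency"`,
#'   `"betweenness"`, `"global_efficiency"`, `"strength"`); defaults to
#'   all of them.
#' @return data.frame with columns `subject`, `session`, `threshold`,
#'   `node` (`NA` for graph-level rows), `measure`, `value`.
#' @export
graph_metric_table <- function(g, cm = NULL, subject = NA_character_,
                               session = NA_character_,
                               measures = c("degree", "path_length",
                                            "clustering",
                                            "local_efficiency",
                                            "betweenness",
                                            "global_efficiency",
                                            "strength")) {
  measures <- match.arg(measures, several.ok = TRUE)
  need_dist <- any(c("path_length", "global_efficiency") %in% measures)
  D <- if (need_dist) shortest_path_lengths(g)

  node_rows <- function(measure, v) {
    data.frame(subject = subject, session = session,
               threshold = g$threshold_r, node = g$labels,
               measure = measure, value = unname(v),
               stringsAsFactors = FALSE)
  }
  graph_row <- function(measure, v) {
    data.frame(subject = subject, session = session,
               threshold = g$threshold_r, node = NA_character_,
               measure = measure, value = v, stringsAsFactors = FALSE)
  }
  out <- list()
  if ("degree" %in% measures) {
    deg <- degrees(g)
    out <- c(out, list(node_rows("degree", deg$per_node),
                       graph_row("degree_mean", deg$mean)))
  }
  if ("path_length" %in% measures) {
    cpl <- characteristic_path_length(g, D)
    out <- c(out, list(node_rows("path_length", cpl$per_node),
                       graph_row("path_length_mean", cpl$mean)))
  }
  if ("clustering" %in% measures) {
    clu <- clustering_coefficients(g)
    out <- c(out, list(node_rows("clustering", clu$per_node),
                       graph_row("clustering_mean", clu$mean)))
  }
  if ("local_efficiency" %in% measures) {
    leff <- local_efficiency(g)
    out <- c(out, list(node_rows("local_efficiency", leff$per_node),
                       graph_row("local_efficiency_mean", leff$mean)))
  }
  if ("betweenness" %in% measures) {
    bc <- if (g$n_nodes >= 3L) betweenness_centrality(g) else
      stats::setNames(rep(NA_real_, g$n_nodes), g$labels)
    out <- c(out, list(node_rows("betweenness", bc)))
  }
  if ("global_efficiency" %in% measures) {
    out <- c(out, list(graph_row("global_efficiency",
                                 global_efficiency(g, D))))
  }
  if ("strength" %in% measures && !is.null(cm)) {
    s <- node_strength(cm)
    out <- c(out, list(node_rows("strength", s$per_node),
                       graph_row("strength_mean", s$mean)))
  }
  do.call(rbind, out)
}
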