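#' Documented toy graph fixtures
#'
#' Small named graphs with exactly known topology, used throughout the test
#' suite and as worked examples for the network measures. Available fixtures:
#' \describe{
#'   \item{`figure1_clustering`}{a central node with three neighbours of
#'     which exactly two neighbour pairs are themselves adjacent, so the
#'     centre has degree 3 and clustering coefficient 2/3.}
#'   \item{`path3`, `path5`}{chains of 3 and 5 nodes.}
#'   \item{`triangle`}{3-cycle.}
#'   \item{`star`}{star on 5 nodes, node 1 the centre.}
#'   \item{`two_cliques`}{two disjoint triangles (6 nodes, 6 edges).}
#'   \item{`two_k4`}{two disjoint complete graphs on 4 nodes.}
#'   \item{`complete_k4`, `complete_k5`}{complete graphs.}
#' }
#'
#' @param name fixture name (see above).
#' @return a `binary_graph`.
#' @examples
#' g <- make_toy_graph("figure1_clustering")
#' degrees(g)$per_node[1]           # 3
#' clustering_coefficients(g)$per_node[1]  # 2/3
#' @export
make_toy_graph <- function(name) {
  complete <- function(n) t(utils::combn(n, 2L))
  path <- function(n) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  edges <- switch(name,
    # centre 1; neighbours 2,3,4; adjacent neighbour pairs (2,3) and (3,4)
    figure1_clustering = rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(3, 4)),
    path3       = path(3L),
    path5       = path(5L),
    triangle    = complete(3L),
    star        = cbind(1L, 2:5),
    two_cliques = rbind(c(1, 2), c(1, 3), c(2, 3),
                        c(4, 5), c(4, 6), c(5, 6)),
    two_k4      = rbind(complete(4L), complete(4L) + 4L),
    complete_k4 = complete(4L),
    complete_k5 = complete(5L),
    stop("unknown toy graph fixture: ", name)
  )
  n <- switch(name,
    figure1_clustering = 4L, path3 = 3L, path5 = 5L, triangle = 3L,
    star = 5L, two_cliques = 6L, two_k4 = 8L, complete_k4 = 4L,
    complete_k5 = 5L)
  binary_graph(edges, n)
}

#' Random graph models
#'
#' Seeded generators for the reference random-graph families used by the
#' null-model and small-world analyses.
#'
#' @param model one of `"erdos_renyi"` (each pair an edge independently with
#'   probability `p`), `"watts_strogatz"` (ring lattice of even degree `k`
#'   with each lattice edge rewired with probability `p`), or
#'   `"ring_lattice"` (each node joined to its `k/2` nearest neighbours on
#'   either side).
#' @param n number of nodes.
#' @param p edge / rewiring probability in \[0, 1\] (ignored for
#'   `ring_lattice`).
#' @param k lattice degree (even; `watts_strogatz` and `ring_lattice` only).
#' @param seed integer RNG seed; same seed reproduces the same graph.
#' @return a `binary_graph`.
#' @export
make_random_graph <- function(model, n, p = NULL, k = NULL, seed = 1L) {
  n <- as.integer(n)
  if (model %in% c("erdos_renyi", "watts_strogatz")) {
    if (is.null(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  }
  if (model %in% c("watts_strogatz", "ring_lattice")) {
    if (is.null(k) || k %% 2L != 0L || k < 2L || k >= n) {
      stop("lattice degree k must be even with 2 <= k < n")
    }
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  if (model == "erdos_renyi") {
    pairs <- t(utils::combn(n, 2L))
    keep <- stats::runif(nrow(pairs)) < p
    return(binary_graph(pairs[keep, , drop = FALSE], n))
  }

  # ring lattice edges: i -- (i + d) mod n for d = 1..k/2
  lat <- do.call(rbind, lapply(seq_len(k %/% 2L), function(d) {
    cbind(seq_len(n), (seq_len(n) + d - 1L) %% n + 1L)
  }))
  if (model == "ring_lattice") return(binary_graph(lat, n))

  # Watts-Strogatz: rewire the far endpoint of each lattice edge with
  # probability p, avoiding self-loops and duplicates
  A <- matrix(FALSE, n, n)
  A[lat] <- TRUE
  A[lat[, c(2L, 1L)]] <- TRUE
  for (e in seq_len(nrow(lat))) {
    if (stats::runif(1L) < p) {
      a <- lat[e, 1L]; b <- lat[e, 2L]
      cand <- which(!A[a, ] & seq_len(n) != a)
      if (length(cand) > 0L) {
        b2 <- cand[sample.int(length(cand), 1L)]
        A[a, b] <- A[b, a] <- FALSE
        A[a, b2] <- A[b2, a] <- TRUE
      }
    }
  }
  graph_from_adjacency(A)
}
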