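#' Degree-preserving rewiring (double-edge swap)
#'
#' Randomizes a graph while conserving every node's degree exactly: two
#' edges (a,b), (c,d) are repeatedly replaced by (a,d), (c,b) whenever the
#' swap creates no self-loop or duplicate edge. This yields the
#' degree-matched random reference networks used for the small-world
#' statistics.
#'
#' @param g a `binary_graph` with at least 2 edges.
#' @param swaps_per_edge target number of successful swaps per edge
#'   (default 10, a common mixing heuristic).
#' @param seed integer RNG seed.
#' @return a rewired `binary_graph`; attribute `"swaps_done"` records the
#'   number of successful swaps, and attribute `"saturated"` is TRUE when
#'   the attempt budget ran out before reaching the target (e.g. complete
#'   graphs admit no legal swap and are returned unchanged).
#' @export
rewire_preserving_degrees <- function(g, swaps_per_edge = 10L, seed = 1L) {
  m <- n_edges(g)
  if (m < 2L) {
    warning("graph too sparse to swap; returned unchanged")
    out <- g
    attr(out, "swaps_done") <- 0L
    attr(out, "saturated") <- TRUE
    return(out)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  E <- g$edges
  A <- adjacency_matrix(g) > 0
  target <- as.integer(swaps_per_edge) * m
  budget <- 20L * target          # bounded retries guarantee termination
  done <- 0L
  tries <- 0L
  # randomness drawn in chunks: edge-pair picks and the orientation flip
  chunk <- 4L * target
  e1 <- sample.int(m, chunk, replace = TRUE)
  e2 <- sample.int(m, chunk, replace = TRUE)
  flip <- stats::runif(chunk) < 0.5
  pos <- 0L
  while (done < target && tries < budget) {
    tries <- tries + 1L
    pos <- pos + 1L
    if (pos > chunk) {
      e1 <- sample.int(m, chunk, replace = TRUE)
      e2 <- sample.int(m, chunk, replace = TRUE)
      flip <- stats::runif(chunk) < 0.5
      pos <- 1L
    }
    if (e1[pos] == e2[pos]) next
    a <- E[e1[pos], 1L]; b <- E[e1[pos], 2L]
    c <- E[e2[pos], 1L]; d <- E[e2[pos], 2L]
    if (flip[pos]) { tmp <- c; c <- d; d <- tmp }
    if (a == c || a == d || b == c || b == d) next
    if (A[a, d] || A[c, b]) next
    A[a, b] <- A[b, a] <- FALSE
    A[c, d] <- A[d, c] <- FALSE
    A[a, d] <- A[d, a] <- TRUE
    A[c, b] <- A[b, c] <- TRUE
    E[e1[pos], 1L] <- min(a, d); E[e1[pos], 2L] <- max(a, d)
    E[e2[pos], 1L] <- min(c, b); E[e2[pos], 2L] <- max(c, b)
    done <- done + 1L
  }
  out <- binary_graph(E, g$n_nodes, threshold_r = g$threshold_r,
                      labels = g$labels)
  attr(out, "swaps_done") <- done
  attr(out, "saturated") <- done < target
  out
}

#' Small-worldness statistics against degree-preserving nulls
#'
#' Compares the mean clustering coefficient and characteristic path length
#' of a graph against their means over `n_null` degree-preserving rewired
#' random graphs: gamma = C_real / C_rand_mean, lambda = L_real /
#' L_rand_mean, and the small-worldness coefficient sigma = gamma / lambda.
#' Sigma above 1 indicates small-world organization (higher clustering
#' than random at comparable path length). Null means and SDs of both
#' parameters are recorded. Per-null seeds are derived from the master
#' seed by counter, so results do not depend on evaluation order.
#'
#' @param g a `binary_graph` with at least one edge.
#' @param n_null number of null graphs (>= 1; 1000 reproduces a typical
#'   full analysis, 100 is adequate for testing).
#' @param seed master seed.
#' @param swaps_per_edge swaps per edge for each rewiring (0 keeps each
#'   null identical to the input).
#' @return a `small_world_result`: list with `C_real`, `L_real`,
#'   `C_rand_mean`, `C_rand_sd`, `L_rand_mean`, `L_rand_sd`, `gamma`,
#'   `lambda`, `sigma`, `n_null`, `seed` and `gamma_defined` (FALSE when
#'   the null mean clustering is zero, leaving gamma undefined).
#' @export
small_worldness <- function(g, n_null = 1000L, seed = 1L,
                            swaps_per_edge = 10L) {
  if (n_edges(g) < 1L) stop("small-worldness requires at least one edge")
  n_null <- as.integer(n_null)
  if (n_null < 1L) stop("n_null must be at least 1")

  C_real <- clustering_coefficients(g)$mean
  L_real <- characteristic_path_length(g)$mean

  seed <- as.integer(seed)
  null_stats <- vapply(seq_len(n_null), function(i) {
    gi <- if (swaps_per_edge > 0L) {
      rewire_preserving_degrees(g, swaps_per_edge,
                                seed = (seed + i) %% .Machine$integer.max)
    } else g
    c(clustering_coefficients(gi)$mean,
      characteristic_path_length(gi)$mean)
  }, numeric(2))

  C_rand_mean <- mean(null_stats[1L, ])
  L_rand_mean <- mean(null_stats[2L, ])
  gamma_defined <- C_rand_mean > 0
  gamma <- if (gamma_defined) C_real / C_rand_mean else NA_real_
  lambda <- L_real / L_rand_mean
  structure(list(
    C_real = C_real, L_real = L_real,
    C_rand_mean = C_rand_mean, C_rand_sd = stats::sd(null_stats[1L, ]),
    L_rand_mean = L_rand_mean, L_rand_sd = stats::sd(null_stats[2L, ]),
    gamma = gamma, lambda = lambda, sigma = gamma / lambda,
    n_null = n_null, seed = seed, gamma_defined = gamma_defined),
    class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf(
    "small_world_result: gamma = %.3f, lambda = %.3f, sigma = %.3f (n_null = %d)\n",
    x$gamma, x$lambda, x$sigma, x$n_null))
  invisible(x)
}

#' Write a small-world result as JSON
#' @param res a `small_world_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_small_world <- function(res, path) {
  jsonlite::write_json(unclass(res), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
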