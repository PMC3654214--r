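#' Newman modularity Q of a partition
#'
#' Q = (1/2a) * sum over modules of sum over node pairs (i, j) in the
#' module of (A_ij - k_i k_j / 2a), where a is the number of edges and k
#' the degrees. Q compares the within-module edge mass against the
#' expectation under a degree-matched random graph.
#'
#' @param g a `binary_graph` with at least one edge.
#' @param membership integer vector assigning every node to a module.
#' @return numeric Q in \[-1, 1\].
#' @export
modularity_q <- function(g, membership) {
  if (length(membership) != g$n_nodes) {
    stop("every node needs a module assignment")
  }
  if (anyNA(membership)) stop("unassigned node(s) in partition")
  m <- n_edges(g)
  if (m < 1L) stop("modularity is undefined on an empty graph")
  A <- adjacency_matrix(g)
  k <- rowSums(A)
  two_a <- 2 * m
  same <- outer(membership, membership, `==`)
  sum((A - outer(k, k) / two_a)[same]) / two_a
}

# one Louvain local-move phase on a weighted graph given as dense matrix W
# (symmetric; diagonal = 2 * self-loop weight so rowSums are degrees).
# Returns the community assignment after no node move improves Q.
.louvain_local_moves <- function(W, order_fn) {
  n <- nrow(W)
  comm <- seq_len(n)
  k <- rowSums(W)
  two_m <- sum(W)
  sigma_tot <- k           # per community (communities start as singletons)
  repeat {
    moved <- FALSE
    for (i in order_fn(n)) {
      ci <- comm[i]
      w_i <- W[i, ]
      # link weight from i to each candidate community (excluding i itself)
      nb <- which(w_i > 0 & seq_len(n) != i)
      if (length(nb) == 0L) next
      cand <- unique(c(ci, comm[nb]))
      k_in <- vapply(cand, function(c) sum(w_i[nb][comm[nb] == c]),
                     numeric(1))
      sig <- sigma_tot[cand] - ifelse(cand == ci, k[i], 0)
      gain <- k_in - k[i] * sig / two_m
      # strict improvement over staying; ties toward the lowest module id
      best <- cand[order(-gain, cand)][1L]
      if (best != ci && gain[cand == best] > gain[cand == ci] + 1e-12) {
        sigma_tot[ci] <- sigma_tot[ci] - k[i]
        sigma_tot[best] <- sigma_tot[best] + k[i]
        comm[i] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  comm
}

#' Louvain community detection
#'
#' Greedy two-phase modularity optimization: nodes are repeatedly moved to
#' the neighbouring module with the largest Q gain (seeded shuffle visit
#' order, ties toward the lowest module id), then the module graph is
#' aggregated and the procedure repeats until Q cannot be improved. The
#' best partition over `n_restarts` seeded restarts is returned.
#'
#' @param g a `binary_graph` with at least one edge.
#' @param seed integer seed controlling the node visit order.
#' @param n_restarts number of independent restarts; the highest-Q
#'   partition wins.
#' @return a `partition`: list with `membership` (integer module ids,
#'   contiguous from 1), `n_modules` and `Q`.
#' @export
louvain_partition <- function(g, seed = 1L, n_restarts = 10L) {
  if (n_edges(g) < 1L) stop("Louvain requires at least one edge")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    memb <- .louvain_once(g)
    q <- modularity_q(g, memb)
    if (is.null(best) || q > best$Q + 1e-12) {
      best <- list(membership = memb, Q = q)
    }
  }
  memb <- match(best$membership, sort(unique(best$membership)))
  names(memb) <- g$labels
  structure(list(membership = memb, n_modules = max(memb), Q = best$Q),
            class = "partition")
}

# full two-phase Louvain run on the current RNG stream
.louvain_once <- function(g) {
  W <- adjacency_matrix(g)
  node_map <- seq_len(g$n_nodes)   # original node -> current super-node
  order_fn <- function(n) sample.int(n)
  repeat {
    comm <- .louvain_local_moves(W, order_fn)
    comm <- match(comm, sort(unique(comm)))
    if (max(comm) == nrow(W)) break       # no merge happened
    node_map <- comm[node_map]
    # aggregate: super-node adjacency; diagonal picks up internal weight
    M <- outer(comm, seq_len(max(comm)), `==`) * 1
    W <- t(M) %*% W %*% M
    if (nrow(W) == 1L) break
  }
  node_map
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d modules, Q = %.4f\n", x$n_modules, x$Q))
  invisible(x)
}

#' Participation coefficients
#'
#' For node j with degree b_j and b_jc edges into module c, the
#' participation coefficient is 1 - sum_c (b_jc / b_j)^2: zero when every
#' edge stays inside the node's own module, approaching one as edges spread
#' evenly over many modules. Isolated nodes score 0 by convention.
#'
#' @param g a `binary_graph`.
#' @param partition a `partition` or a bare membership vector.
#' @return list with `per_node` (named numeric in \[0, 1\]), `link_counts`
#'   (node x module matrix of b_jc) and `degree` (b_j).
#' @export
participation_coefficients <- function(g, partition) {
  memb <- if (inherits(partition, "partition")) partition$membership
          else as.integer(partition)
  if (length(memb) != g$n_nodes) stop("every node needs a module assignment")
  if (anyNA(memb)) stop("unassigned node(s) in partition")
  A <- adjacency_matrix(g)
  mods <- sort(unique(memb))
  bjc <- vapply(mods, function(c) rowSums(A[, memb == c, drop = FALSE]),
                numeric(g$n_nodes))
  bjc <- matrix(bjc, nrow = g$n_nodes,
                dimnames = list(g$labels, paste0("module", mods)))
  bj <- rowSums(bjc)
  omega <- ifelse(bj > 0, 1 - rowSums((bjc / pmax(bj, 1))^2), 0)
  names(omega) <- g$labels
  list(per_node = omega, link_counts = bjc, degree = bj)
}

#' Write a partition as a two-column TSV plus membership JSON
#' @param partition a `partition`.
#' @param path output TSV path (`node`, `module`); a `.json` sidecar with
#'   per-module member lists is written alongside.
#' @return the path, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(node = names(partition$membership),
                   module = unname(partition$membership))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  members <- split(df$node, df$module)
  jsonlite::write_json(
    list(Q = partition$Q, n_modules = partition$n_modules,
         modules = members),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
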