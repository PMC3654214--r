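# Independent brute-force oracles. These deliberately use the naive
# textbook formulation of every quantity (explicit loops, exhaustive path
# enumeration) and share no code with the package implementations.

# all-pairs shortest paths by Floyd-Warshall
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# clustering coefficient by explicit neighbour-pair counting
oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    d <- length(nb)
    if (d < 2) return(0)
    r <- 0
    for (a in seq_len(d - 1)) {
      for (b in (a + 1):d) {
        if (A[nb[a], nb[b]] > 0) r <- r + 1
      }
    }
    r / (d * (d - 1) / 2)
  }, numeric(1))
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
    }
  }
  tot / (n * (n - 1))
}

# local efficiency by explicit neighbour-subgraph extraction
oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

# betweenness by exhaustive enumeration of every shortest path
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  enum_paths <- function(f, j) {
    # all shortest f->j paths as vectors of visited nodes (excluding f)
    recurse <- function(v) {
      if (v == j) return(list(integer(0)))
      out <- list()
      for (w in which(A[v, ] > 0)) {
        if (D[f, w] == D[f, v] + 1 && D[f, w] + D[w, j] == D[f, j]) {
          for (tail in recurse(w)) out <- c(out, list(c(w, tail)))
        }
      }
      out
    }
    recurse(f)
  }
  bc <- numeric(n)
  for (f in seq_len(n)) {
    for (j in seq_len(n)) {
      if (f == j || !is.finite(D[f, j])) next
      paths <- enum_paths(f, j)
      y <- length(paths)
      for (i in setdiff(seq_len(n), c(f, j))) {
        through <- sum(vapply(paths, function(p) i %in% p, logical(1)))
        bc[i] <- bc[i] + through / y
      }
    }
  }
  bc / ((n - 1) * (n - 2))
}

# modularity by naive term-by-term summation of the defining formula
oracle_modularity <- function(A, membership) {
  m <- sum(A) / 2
  k <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + A[i, j] - k[i] * k[j] / (2 * m)
      }
    }
  }
  q / (2 * m)
}

# participation coefficient by per-node per-module tally
oracle_participation <- function(A, membership) {
  n <- nrow(A)
  vapply(seq_len(n), function(j) {
    nb <- which(A[j, ] > 0)
    bj <- length(nb)
    if (bj == 0) return(0)
    s <- 0
    for (c in unique(membership)) {
      bjc <- sum(membership[nb] == c)
      s <- s + (bjc / bj)^2
    }
    1 - s
  }, numeric(1))
}

# seeded small random graph for the oracle-equivalence suites
random_oracle_graph <- function(seed, n_max = 10L) {
  set.seed(seed)
  n <- sample(4:n_max, 1L)
  p <- runif(1, 0.2, 0.7)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(runif(length(up)) < p)
  A <- A + t(A)
  list(A = A, g = graph_from_adjacency(A))
}
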