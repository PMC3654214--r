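test_that("degrees and the handshake lemma hold on fixtures and random graphs", {
  expect_equal(unname(degrees(make_toy_graph("complete_k5"))$per_node),
               rep(4, 5))
  expect_equal(degrees(make_toy_graph("complete_k5"))$mean, 4)
  empty <- binary_graph(NULL, 4)
  expect_equal(unname(degrees(empty)$per_node), rep(0L, 4))

  for (s in 1:25) {
    og <- random_oracle_graph(s)
    expect_equal(sum(degrees(og$g)$per_node), 2 * n_edges(og$g))
  }
})

test_that("shortest paths match Floyd-Warshall and flag unreachable pairs", {
  p5 <- make_toy_graph("path5")
  D <- shortest_path_lengths(p5)
  expect_equal(D[1, 5], 4)

  k5 <- make_toy_graph("complete_k5")
  Dk <- shortest_path_lengths(k5)
  expect_true(all(Dk[upper.tri(Dk)] == 1))

  tc <- make_toy_graph("two_cliques")
  expect_true(all(is.infinite(shortest_path_lengths(tc)[1:3, 4:6])))

  for (s in 1:30) {
    og <- random_oracle_graph(s)
    expect_equal(shortest_path_lengths(og$g), oracle_distances(og$A),
                 ignore_attr = TRUE)
  }
})

test_that("characteristic path length averages finite distances", {
  expect_equal(characteristic_path_length(make_toy_graph("complete_k5"))$mean,
               1)
  expect_equal(characteristic_path_length(make_toy_graph("path5"))$mean, 2)
  # two disconnected triangles: every finite distance is 1
  expect_equal(characteristic_path_length(make_toy_graph("two_cliques"))$mean,
               1)
  # edgeless graph: undefined, flagged
  res <- characteristic_path_length(binary_graph(NULL, 3))
  expect_false(res$defined)
  expect_true(is.na(res$mean))
})

test_that("global efficiency equals the ordered-pair inverse-distance mean", {
  expect_equal(global_efficiency(make_toy_graph("complete_k5")), 1)
  expect_equal(global_efficiency(binary_graph(NULL, 5)), 0)
  # path5: (4*1 + 3*(1/2) + 2*(1/3) + 1*(1/4)) / 10 unordered pairs
  expect_equal(global_efficiency(make_toy_graph("path5")),
               (4 + 3 / 2 + 2 / 3 + 1 / 4) / 10, tolerance = 1e-12)

  for (s in 1:30) {
    og <- random_oracle_graph(s)
    expect_equal(global_efficiency(og$g), oracle_global_efficiency(og$A),
                 tolerance = 1e-12)
  }
})

test_that("Jensen bound: global efficiency >= 1/L on connected graphs", {
  for (s in 1:30) {
    og <- random_oracle_graph(s)
    D <- shortest_path_lengths(og$g)
    if (any(is.infinite(D))) next
    expect_gte(global_efficiency(og$g),
               1 / characteristic_path_length(og$g)$mean - 1e-12)
  }
})

test_that("clustering matches the triangle-ratio definition", {
  f1 <- make_toy_graph("figure1_clustering")
  expect_equal(unname(clustering_coefficients(f1)$per_node[1]), 2 / 3)
  expect_equal(unname(clustering_coefficients(
    make_toy_graph("complete_k4"))$per_node), rep(1, 4))
  expect_equal(unname(clustering_coefficients(
    make_toy_graph("star"))$per_node[1]), 0)

  for (s in 1:30) {
    og <- random_oracle_graph(s)
    expect_equal(unname(clustering_coefficients(og$g)$per_node),
                 oracle_clustering(og$A), tolerance = 1e-12)
  }
})

test_that("local efficiency matches brute-force subgraph efficiency", {
  expect_equal(unname(local_efficiency(
    make_toy_graph("complete_k4"))$per_node), rep(1, 4))
  # degree-1 nodes score 0 by convention
  expect_equal(unname(local_efficiency(make_toy_graph("path5"))$per_node[1]),
               0)
  for (s in 1:25) {
    og <- random_oracle_graph(s)
    expect_equal(unname(local_efficiency(og$g)$per_node),
                 oracle_local_efficiency(og$A), tolerance = 1e-12)
  }
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  p3 <- make_toy_graph("path3")
  expect_equal(unname(betweenness_centrality(p3)), c(0, 1, 0))
  expect_equal(unname(betweenness_centrality(make_toy_graph("complete_k5"))),
               rep(0, 5))
  expect_error(binary_graph(rbind(c(1, 2)), 2) |> betweenness_centrality(),
               "at least 3")

  for (s in 1:20) {
    og <- random_oracle_graph(s, n_max = 8L)
    expect_equal(unname(betweenness_centrality(og$g)),
                 oracle_betweenness(og$A), tolerance = 1e-12)
  }
})

test_that("betweenness agrees with igraph up to its normalization", {
  skip_if_not_installed("igraph")
  for (s in c(3, 14, 27)) {
    og <- random_oracle_graph(s)
    ig <- igraph::graph_from_adjacency_matrix(og$A, mode = "undirected")
    n <- nrow(og$A)
    expect_equal(unname(betweenness_centrality(og$g)),
                 igraph::betweenness(ig) * 2 / ((n - 1) * (n - 2)),
                 tolerance = 1e-10)
  }
})

test_that("hub identification ranks by the chosen measure, ties by label order", {
  star <- make_toy_graph("star")
  expect_equal(identify_hubs(star, "degree", 1), "n1")
  expect_equal(identify_hubs(make_toy_graph("path5"), "betweenness", 1), "n3")
  expect_equal(identify_hubs(make_toy_graph("complete_k4"), "degree", 2),
               c("n1", "n2"))
  expect_error(identify_hubs(star, "degree", 9), "between 1 and")
})

test_that("degree histogram covers all nodes and respects its bins", {
  k5 <- make_toy_graph("complete_k5")
  h <- degree_distribution(k5, seq(-0.5, 4.5, 1))
  expect_equal(unname(h), c(0, 0, 0, 0, 5))
  p5 <- make_toy_graph("path5")
  h5 <- degree_distribution(p5, seq(0.5, 2.5, 1))
  expect_equal(unname(h5), c(2, 3))
  expect_error(degree_distribution(k5, c(0.5, 1.5)), "outside")
})

test_that("adding an edge never decreases degree or global efficiency", {
  for (s in 1:15) {
    og <- random_oracle_graph(s)
    A <- og$A
    miss <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(miss) == 0L) next
    pick <- miss[1L, ]
    A2 <- A
    A2[pick[1L], pick[2L]] <- A2[pick[2L], pick[1L]] <- 1
    g2 <- graph_from_adjacency(A2)
    expect_true(all(degrees(g2)$per_node >= degrees(og$g)$per_node))
    expect_gte(global_efficiency(g2), global_efficiency(og$g) - 1e-12)
  }
})
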