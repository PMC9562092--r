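two_triangle_bridge <- function() {
  W <- matrix(0, 6, 6)
  tri <- function(W, a, b, c, w = 1) {
    for (p in list(c(a, b), c(b, c), c(c, a))) {
      W[p[1], p[2]] <- w
      W[p[2], p[1]] <- w
    }
    W
  }
  W <- tri(W, 1, 2, 3)
  W <- tri(W, 4, 5, 6)
  W[3, 4] <- 0.5
  W
}

test_that("percolation threshold preserves the giant component", {
  W <- two_triangle_bridge()
  res <- percolation_threshold(W)
  expect_equal(res$tau, 0.5)
  expect_equal(res$giant_size, 6)
  expect_gt(res$W[3, 4], 0)          # bridge retained

  # complete graph with equal weights is untouched
  C <- matrix(0.7, 4, 4)
  diag(C) <- 0
  rc <- percolation_threshold(C)
  expect_equal(rc$tau, 0.7)
  expect_identical(rc$W, C)

  # star: removing any edge disconnects a leaf
  S <- matrix(0, 4, 4)
  S[1, 2] <- 0.9
  S[1, 3] <- 0.8
  S[1, 4] <- 0.7
  expect_equal(percolation_threshold(S)$tau, 0.7)

  empty <- matrix(0, 3, 3)
  re <- percolation_threshold(empty)
  expect_equal(re$tau, 0)
  expect_identical(re$W, empty)
})

test_that("bisected percolation equals the exhaustive scan on random graphs", {
  for (s in 1:30) {
    W <- random_digraph(7, p = 0.3, seed = s)
    expect_equal(percolation_threshold(W)$tau, oracle_percolation_tau(W))
  }
})

test_that("weight-to-length mapping inverts and orders weights", {
  W <- matrix(0, 2, 2)
  W[1, 2] <- 0.5
  D <- weights_to_lengths(W)
  expect_equal(D[1, 2], 2)
  expect_equal(D[2, 1], Inf)
  w <- c(0.2, 0.5, 0.9)
  d <- 1 / w
  expect_true(all(diff(d) < 0))      # larger weight, shorter length
})

test_that("shortest paths match hand routes and the Floyd-Warshall oracle", {
  # chain a -> b -> c
  D0 <- matrix(Inf, 3, 3)
  D0[1, 2] <- 1
  D0[2, 3] <- 1
  D <- shortest_paths_matrix(D0)
  expect_equal(D[1, 3], 2)
  expect_equal(D[3, 1], Inf)
  # two-hop route beats a slow direct edge
  E0 <- matrix(Inf, 3, 3)
  E0[1, 3] <- 5
  E0[1, 2] <- 1
  E0[2, 3] <- 1
  expect_equal(shortest_paths_matrix(E0)[1, 3], 2)
  for (s in 1:20) {
    W <- random_digraph(8, p = 0.35, seed = 100 + s)
    L <- weights_to_lengths(W)
    expect_equal(shortest_paths_matrix(L), oracle_floyd_warshall(L),
                 ignore_attr = TRUE)
  }
})

test_that("CPL and GE match hand-enumerated values", {
  # complete unit-weight digraph
  Cw <- matrix(1, 4, 4)
  diag(Cw) <- 0
  D <- shortest_paths_matrix(weights_to_lengths(Cw))
  expect_equal(as.numeric(cpl(D)), 1)
  expect_equal(global_efficiency(D), 1)

  # directed 3-cycle: ordered pairs alternate distance 1 and 2
  cyc <- matrix(0, 3, 3)
  cyc[1, 2] <- 1
  cyc[2, 3] <- 1
  cyc[3, 1] <- 1
  Dc <- shortest_paths_matrix(weights_to_lengths(cyc))
  expect_equal(as.numeric(cpl(Dc)), 1.5)
  expect_equal(global_efficiency(Dc), 0.75)

  # a shortcut never increases CPL
  with_short <- cyc
  with_short[1, 3] <- 1
  Ds <- shortest_paths_matrix(weights_to_lengths(with_short))
  expect_lte(as.numeric(cpl(Ds)), as.numeric(cpl(Dc)))

  expect_equal(global_efficiency(shortest_paths_matrix(
    weights_to_lengths(matrix(0, 3, 3)))), 0)
  expect_error(cpl(shortest_paths_matrix(weights_to_lengths(matrix(0, 3, 3)))),
               "No finite")
})

test_that("directed clustering matches its formula on the unit triangle", {
  Tri <- matrix(1, 3, 3)
  diag(Tri) <- 0
  expect_equal(clustering_directed(Tri), rep(1, 3), ignore_attr = TRUE)
  # a node with fewer than two neighbors has no triangles
  P <- matrix(0, 3, 3)
  P[1, 2] <- 1
  expect_equal(clustering_directed(P), rep(0, 3), ignore_attr = TRUE)
})

test_that("clustering and local efficiency match brute-force oracles", {
  for (s in 1:30) {
    W <- random_digraph(6, p = 0.45, seed = 200 + s)
    expect_equal(clustering_directed(W), oracle_cc(W), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(local_efficiency_directed(W), oracle_le(W), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # binary graphs too
  for (s in 1:10) {
    W <- (random_digraph(6, p = 0.5, seed = 300 + s) > 0) * 1
    expect_equal(clustering_directed(W), oracle_cc(W), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # isolated node
  iso <- matrix(0, 4, 4)
  iso[2, 3] <- 1
  iso[3, 2] <- 1
  expect_equal(local_efficiency_directed(iso)[1], 0, ignore_attr = TRUE)
  # bidirectional unit triangle: hand-enumerable neighbor subgraphs
  Tri <- matrix(1, 3, 3)
  diag(Tri) <- 0
  le <- local_efficiency_directed(Tri)
  expect_true(all(le > 0))
  expect_equal(le, oracle_le(Tri), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("global metrics are invariant to node relabeling", {
  set.seed(9)
  W <- random_digraph(8, p = 0.4)
  D <- shortest_paths_matrix(weights_to_lengths(W))
  perm <- sample(8)
  Wp <- W[perm, perm]
  Dp <- shortest_paths_matrix(weights_to_lengths(Wp))
  expect_equal(as.numeric(cpl(D)), as.numeric(cpl(Dp)), tolerance = 1e-12)
  expect_equal(global_efficiency(D), global_efficiency(Dp), tolerance = 1e-12)
})

test_that("the metrics table is long, consistent and deterministic", {
  set.seed(10)
  adjacency <- lapply(1:4, function(b) {
    list(theta = random_digraph(9, 0.4), alpha = random_digraph(9, 0.4))
  })
  keys <- tibble::tibble(subject = c(1, 1, 2, 2), block = c(1, 2, 1, 2),
                         condition = c("None", "H", "None", "H"))
  tab <- summarize_graph_metrics(adjacency, keys = keys)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$cc_mean, vapply(seq_len(8), function(i) mean(tab$cc[[i]]),
                                   numeric(1)))
  tab2 <- summarize_graph_metrics(adjacency, keys = keys)
  expect_identical(dplyr::select(tab, -cc, -le), dplyr::select(tab2, -cc, -le))
})
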