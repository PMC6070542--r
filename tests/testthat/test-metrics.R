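test_that("shortest path lengths use the inverse-weight length transform", {
  two <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  d <- shortest_path_lengths(two)
  expect_equal(d[1, 2], 2)
  expect_equal(diag(d), c(0, 0))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(shortest_path_lengths(path)[1, 3], 2)

  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(shortest_path_lengths(neg), "negative")
})

test_that("all four metrics agree with brute-force oracles on random graphs", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    W <- rand_weight_matrix(n, density = runif(1, 0.3, 0.9))
    D <- fw_oracle(W)
    expect_equal(shortest_path_lengths(W), D, tolerance = 1e-12)

    inv <- 1 / D
    diag(inv) <- 0
    expect_equal(global_efficiency(W), sum(inv) / (n * (n - 1)),
                 tolerance = 1e-12)

    off <- D[row(D) != col(D)]
    fin <- off[is.finite(off)]
    cpl <- characteristic_path_length(W)
    if (length(fin)) expect_equal(cpl$L_w, mean(fin), tolerance = 1e-12)
    expect_equal(cpl$n_connected_pairs, length(fin))

    expect_equal(clustering_coefficient(W), cw_oracle(W), tolerance = 1e-12)
    expect_equal(local_efficiency(W), eloc_oracle(W), tolerance = 1e-12)
  }
})

test_that("canonical small graphs give the textbook values", {
  tri <- matrix(1, 3, 3)
  diag(tri) <- 0
  expect_equal(global_efficiency(tri), 1)
  expect_equal(characteristic_path_length(tri)$L_w, 1)
  expect_equal(clustering_coefficient(tri), 1)
  expect_equal(local_efficiency(tri), 1)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(clustering_coefficient(star), 0)
  expect_equal(local_efficiency(star), 0)

  two <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  expect_equal(global_efficiency(two), 0.3)

  # two disconnected dyads: L_w averages the 4 finite ordered pairs
  dy <- matrix(0, 4, 4)
  dy[1, 2] <- dy[2, 1] <- dy[3, 4] <- dy[4, 3] <- 0.5
  cpl <- characteristic_path_length(dy)
  expect_equal(cpl$L_w, 2)
  expect_equal(cpl$n_connected_pairs, 4)

  empty <- matrix(0, 4, 4)
  expect_equal(global_efficiency(empty), 0)
  expect_true(is.na(characteristic_path_length(empty)$L_w))
})

test_that("metrics are scale-covariant (E ~ c, L ~ 1/c)", {
  set.seed(77)
  W <- rand_weight_matrix(10, density = 0.5)
  base <- network_metrics(W)
  for (c in c(0.25, 43.2)) {
    scaled <- network_metrics(c * W)
    expect_equal(scaled$E_glob, c * base$E_glob, tolerance = 1e-9)
    expect_equal(scaled$C_w, c * base$C_w, tolerance = 1e-9)
    expect_equal(scaled$E_loc, c * base$E_loc, tolerance = 1e-9)
    expect_equal(scaled$L_w, base$L_w / c, tolerance = 1e-9)
  }
  # cost normalization is exactly such a rescaling
  cn <- network_metrics(cost_normalize(W))
  cost <- sum(W[upper.tri(W)])
  expect_equal(cn$E_glob * cost, base$E_glob, tolerance = 1e-9)
  expect_equal(cn$L_w / cost, base$L_w, tolerance = 1e-9)
})

test_that("binary-weight networks reduce to binary graph metrics", {
  set.seed(55)
  W <- rand_weight_matrix(8, density = 0.5)
  B <- (W > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  dbin <- igraph::distances(g)   # unweighted BFS distances
  expect_equal(shortest_path_lengths(B), dbin, ignore_attr = TRUE)
  off <- dbin[row(dbin) != col(dbin)]
  fin <- off[is.finite(off)]
  expect_equal(characteristic_path_length(B)$L_w, mean(fin))
  expect_equal(clustering_coefficient(B),
               mean(igraph::transitivity(g, type = "localundirected",
                                         isolates = "zero")))
})

test_that("node relabeling leaves every metric unchanged", {
  set.seed(33)
  W <- rand_weight_matrix(9, density = 0.4)
  perm <- sample(9)
  Wp <- W[perm, perm]
  a <- network_metrics(W)
  b <- network_metrics(Wp)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("metrics on [0,1] weights respect their upper bounds", {
  set.seed(21)
  for (rep in 1:5) {
    W <- rand_weight_matrix(10, density = runif(1, 0.2, 1), wmax = 1)
    expect_lte(global_efficiency(W), 1 + 1e-12)
    expect_lte(clustering_coefficient(W), 1 + 1e-12)
  }
})
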