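# Independent oracles and fixture builders. Everything here is written
# from first principles (loops, enumeration) or routed through a
# different library code path than the implementation it checks.

# Random symmetric weight matrix with given edge density (uses the
# caller's RNG stream; wrap in withr::with_seed or set.seed).
rand_weight_matrix <- function(n, density = 0.6, wmin = 0.05, wmax = 1) {
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m))
  on <- runif(length(ut)) < density
  m[ut[on]] <- runif(sum(on), wmin, wmax)
  m + t(m)
}

# Floyd-Warshall all-pairs distances, explicit triple loop, on edge
# lengths 1/w (independent of the package's Dijkstra route).
fw_oracle <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[W > 0] <- 1 / W[W > 0]
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Onnela clustering by exhaustive triple enumeration.
cw_oracle <- function(W) {
  n <- nrow(W)
  ci <- numeric(n)
  for (i in 1:n) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tot <- 0
    for (j in nb) for (h in nb)
      if (j != h) tot <- tot + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    ci[i] <- tot / (k * (k - 1))
  }
  mean(ci)
}

# Local efficiency by direct per-node evaluation with subgraph distances
# from igraph (different shortest-path route than the implementation).
eloc_oracle <- function(W) {
  n <- nrow(W)
  ei <- numeric(n)
  for (i in 1:n) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- W[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    d <- if (igraph::ecount(g) > 0)
      igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    else matrix(Inf, k, k)
    tot <- 0
    for (a in 1:k) for (b in 1:k)
      if (a != b && is.finite(d[a, b]))
        tot <- tot + (W[i, nb[a]] * W[i, nb[b]] / d[a, b])^(1 / 3)
    ei[i] <- tot / (k * (k - 1))
  }
  mean(ei)
}

# Two-way ANOVA sums of squares from first principles (explicit loops),
# then McGraw-Wong ICC(A,1).
icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(x[i, ]) - gm)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (mean(x[, j]) - gm)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + gm)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Small synthetic cohort for fast unit tests.
small_cohort <- function(seed = 1, n_nodes = 16, n_subjects = 6, ...) {
  generate_cohort(synthetic_config(n_nodes = n_nodes,
                                   n_subjects = n_subjects,
                                   seed = seed, ...))
}
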