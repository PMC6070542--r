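#' All-pairs shortest path lengths of a weighted network
#'
#' Edge lengths are the reciprocals of the connection weights
#' (`l_ij = 1/w_ij`; stronger connections are "shorter"), the standard
#' connection-length transform for connectivity-probability weights.
#' Distances are computed with Dijkstra's algorithm (via igraph);
#' disconnected pairs get `Inf` and the diagonal is 0.
#'
#' @param W Symmetric non-negative weight matrix.
#' @return Symmetric matrix of shortest path lengths.
#' @export
shortest_path_lengths <- function(W) {
  assert_square_matrix(W, "W")
  if (min(W) < 0) stop("negative weights are not allowed", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0L) {
    d <- matrix(Inf, nrow(W), ncol(W))
    diag(d) <- 0
    dimnames(d) <- dimnames(W)
    return(d)
  }
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- dimnames(W)
  d
}

#' Weighted global efficiency
#'
#' Mean inverse shortest path length over all ordered node pairs,
#' `E_glob = 1/(n(n-1)) * sum_{i != j} 1/d_ij`, with `1/Inf = 0` for
#' disconnected pairs. For weights in \[0, 1\] (no rescaling),
#' `E_glob <= 1`.
#'
#' @param W Symmetric non-negative weight matrix, n >= 2.
#' @return Global efficiency.
#' @export
global_efficiency <- function(W) {
  n <- nrow(assert_square_matrix(W, "W"))
  if (n < 2) stop("global efficiency needs at least 2 nodes", call. = FALSE)
  d <- shortest_path_lengths(W)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted characteristic path length
#'
#' Mean shortest path length over connected ordered node pairs;
#' disconnected pairs are excluded rather than imputed, and the number of
#' connected pairs is reported so the exclusion is visible. A network
#' with no connected pair has an undefined path length (`NA`).
#'
#' @param W Symmetric non-negative weight matrix.
#' @return List with `L_w` (mean finite distance, `NA` if none) and
#'   `n_connected_pairs` (ordered pairs with finite distance).
#' @export
characteristic_path_length <- function(W) {
  d <- shortest_path_lengths(W)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  list(L_w = if (length(finite)) mean(finite) else NA_real_,
       n_connected_pairs = length(finite))
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per node, the geometric-mean intensity of closed triangles around it:
#' `C_i = 1/(k_i (k_i - 1)) * sum_{j,h} (w_ij w_ih w_jh)^(1/3)` over
#' ordered neighbor pairs, with `C_i = 0` for degree `k_i < 2`; the
#' network coefficient is the mean of `C_i` over all nodes. Weights are
#' used as-is (no max-weight rescaling), which keeps the coefficient
#' linearly scale-covariant: `C_w(c W) = c C_w(W)`.
#'
#' @param W Symmetric non-negative weight matrix.
#' @return Network clustering coefficient.
#' @export
clustering_coefficient <- function(W) {
  assert_square_matrix(W, "W")
  if (min(W) < 0) stop("negative weights are not allowed", call. = FALSE)
  W3 <- W^(1 / 3)
  cyc <- diag(W3 %*% W3 %*% W3)
  k <- rowSums(W > 0)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, cyc / denom, 0)
  mean(ci)
}

#' Weighted local efficiency
#'
#' For each node i with degree `k_i >= 2`, the efficiency of its
#' neighbor-induced subgraph:
#' `E_loc(i) = 1/(k_i (k_i - 1)) * sum_{j != h in N_i}
#' (w_ij w_ih / d_jh(N_i))^(1/3)`, where `d_jh(N_i)` is the shortest
#' path length between neighbors j and h within the subgraph induced by
#' `N_i` (edge lengths `1/w`). Nodes with fewer than 2 neighbors
#' contribute 0. The network value is the mean over all nodes. The
#' neighbor-subgraph distances run in compiled code (Floyd-Warshall on
#' the induced subgraph), as the innermost loop of the threshold sweep.
#'
#' @param W Symmetric non-negative weight matrix.
#' @return Network local efficiency.
#' @export
local_efficiency <- function(W) {
  assert_square_matrix(W, "W")
  if (min(W) < 0) stop("negative weights are not allowed", call. = FALSE)
  .eloc_cpp(W)
}

#' All four weighted network metrics of one network
#'
#' Convenience wrapper computing any subset of global efficiency, local
#' efficiency, clustering coefficient and characteristic path length in
#' one pass (the shortest-path matrix is shared between `E_glob` and
#' `L_w`).
#'
#' @param W Symmetric non-negative weight matrix.
#' @param metrics Character subset of
#'   `c("E_glob", "E_loc", "C_w", "L_w")`.
#' @return Named list with the requested metrics plus
#'   `n_connected_pairs` when `L_w` is requested.
#' @export
network_metrics <- function(W,
                            metrics = c("E_glob", "E_loc", "C_w", "L_w")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list()
  if (any(c("E_glob", "L_w") %in% metrics)) {
    d <- shortest_path_lengths(W)
    n <- nrow(W)
    if ("E_glob" %in% metrics) {
      inv <- 1 / d
      diag(inv) <- 0
      out$E_glob <- sum(inv) / (n * (n - 1))
    }
    if ("L_w" %in% metrics) {
      off <- d[row(d) != col(d)]
      finite <- off[is.finite(off)]
      out$L_w <- if (length(finite)) mean(finite) else NA_real_
      out$n_connected_pairs <- length(finite)
    }
  }
  if ("C_w" %in% metrics) out$C_w <- clustering_coefficient(W)
  if ("E_loc" %in% metrics) out$E_loc <- local_efficiency(W)
  out[c(intersect(c("E_glob", "E_loc", "C_w", "L_w"), metrics),
        if ("L_w" %in% metrics) "n_connected_pairs")]
}
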