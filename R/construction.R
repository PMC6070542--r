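#' Average directed connection probabilities into a symmetric matrix
#'
#' Probabilistic tractography yields a probability from region i to j and
#' another from j to i; the undirected connectivity is their average:
#' `out[i, j] = (p_forward[i, j] + p_backward[j, i]) / 2`, with the
#' diagonal zeroed.
#'
#' @param p_forward,p_backward n x n matrices of directed probabilities
#'   in \[0, 1\].
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
symmetrize <- function(p_forward, p_backward) {
  assert_square_matrix(p_forward, "p_forward")
  assert_square_matrix(p_backward, "p_backward")
  if (!all(dim(p_forward) == dim(p_backward)))
    stop("'p_forward' and 'p_backward' have different dimensions",
         call. = FALSE)
  if (min(p_forward) < 0 || min(p_backward) < 0 ||
      max(p_forward) > 1 || max(p_backward) > 1)
    stop("directed probabilities must lie in [0, 1]", call. = FALSE)
  # per unordered pair {i, j} (i < j): average p_forward[i, j] with
  # p_backward[j, i], then mirror into a symmetric matrix
  avg <- (p_forward + t(p_backward)) / 2
  n <- nrow(avg)
  out <- matrix(0, n, n, dimnames = dimnames(p_forward))
  out[upper.tri(out)] <- avg[upper.tri(avg)]
  out + t(out)
}

#' Inclusive arithmetic sequence of connectivity thresholds
#'
#' @param start,stop Range of thresholds, `start < stop` (equal gives the
#'   single value `start`).
#' @param step Positive increment. The endpoint is included when
#'   `stop - start` is an integer multiple of `step` within 1e-9.
#' @return Numeric vector of thresholds.
#' @examples
#' length(threshold_sweep(0.01, 0.10, 0.0025))  # 37
#' @export
threshold_sweep <- function(start, stop, step) {
  assert_scalar_number(step, "step", lower = 0, strict_lower = TRUE)
  if (stop < start) stop("'start' must be <= 'stop'", call. = FALSE)
  n_steps <- floor((stop - start) / step + 1e-9)
  start + step * seq(0, n_steps)
}

# internal constructor for edge masks
edge_mask <- function(mask, threshold, strategy, session_scope = "pooled") {
  structure(list(mask = mask, threshold = threshold, strategy = strategy,
                 session_scope = session_scope),
            class = "connrep_edge_mask")
}

#' @export
print.connrep_edge_mask <- function(x, ...) {
  cat(sprintf("edge mask (%s, %s): threshold %g, sparsity %.4f\n",
              x$strategy, x$session_scope, x$threshold, sparsity(x)))
  invisible(x)
}

#' Group-level connectivity threshold mask
#'
#' An edge is removed for the whole group when the group mean of its
#' connectivity probability plus two sample standard deviations falls
#' below the threshold: `mean(P_ij) + 2 * sd(P_ij) < threshold` (strict;
#' ties retain the edge). Under the `common` strategy the statistic pools
#' every scan from both sessions, so all subjects and both sessions share
#' one mask (hence identical sparsity). Under the `separate` strategy the
#' rule is evaluated once per session, and the per-session masks may
#' differ.
#'
#' @param scans Either a [cohort()] or a flat list of symmetric
#'   connectivity matrices (at least 2).
#' @param threshold Positive connectivity threshold.
#' @param strategy `"common"` or `"separate"` (`separate` requires a
#'   cohort, since scans must be grouped by session).
#' @return For `common`, one `connrep_edge_mask`; for `separate`, a named
#'   list of masks, one per session.
#' @export
group_threshold_mask <- function(scans, threshold,
                                 strategy = c("common", "separate")) {
  strategy <- match.arg(strategy)
  assert_scalar_number(threshold, "threshold", lower = 0,
                       strict_lower = TRUE)
  if (strategy == "separate") {
    if (!inherits(scans, "connrep_cohort"))
      stop("'separate' strategy requires a cohort (scans grouped by session)",
           call. = FALSE)
    masks <- lapply(scans$sessions, function(r)
      build_mask(cohort_scan_list(scans, sessions = r), threshold,
                 "separate", r))
    return(setNames(masks, scans$sessions))
  }
  if (inherits(scans, "connrep_cohort")) scans <- cohort_scan_list(scans)
  build_mask(scans, threshold, "common", "pooled")
}

build_mask <- function(scan_list, threshold, strategy, scope) {
  if (length(scan_list) < 2L)
    stop("at least 2 scans are required (sd is undefined otherwise)",
         call. = FALSE)
  n <- nrow(scan_list[[1]])
  vals <- vapply(scan_list, upper_tri_values,
                 numeric(n * (n - 1) / 2))
  m <- ncol(vals)
  mu <- rowMeans(vals)
  sdv <- sqrt(rowSums((vals - mu)^2) / (m - 1))
  keep <- !(mu + 2 * sdv < threshold)
  m <- matrix_from_upper_tri(as.numeric(keep), n,
                             colnames(scan_list[[1]])) > 0
  diag(m) <- FALSE
  edge_mask(m, threshold, strategy, scope)
}

#' Sparsity of an edge mask
#'
#' Fraction of possible edges retained: retained upper-triangle entries
#' divided by `n (n - 1) / 2` (3003 for 78 nodes).
#'
#' @param mask A `connrep_edge_mask` or a logical/numeric symmetric matrix.
#' @return Sparsity in \[0, 1\].
#' @export
sparsity <- function(mask) {
  m <- if (inherits(mask, "connrep_edge_mask")) mask$mask else mask
  assert_square_matrix(m * 1, "mask")
  v <- upper_tri_values(m)
  sum(v != 0) / length(v)
}

#' Zero out edges excluded by a mask
#'
#' @param scan Symmetric connectivity matrix (or a cohort scan).
#' @param mask A `connrep_edge_mask` or logical matrix of the same size.
#' @return Matrix with masked-out entries set to zero.
#' @export
apply_mask <- function(scan, mask) {
  m <- if (inherits(mask, "connrep_edge_mask")) mask$mask else mask
  assert_square_matrix(scan, "scan")
  if (!all(dim(scan) == dim(m)))
    stop("scan and mask dimensions differ", call. = FALSE)
  scan * (m != 0)
}

#' Cost-normalize a weighted network
#'
#' Divides every weight by the total network cost (the sum of weights
#' over the strict upper triangle), so that every subject's network has
#' unit total cost. Since the four network metrics are scale-covariant,
#' this removes global between-subject scale differences while preserving
#' topology and relative weights.
#'
#' @param scan Symmetric non-negative weight matrix with at least one
#'   non-zero edge.
#' @return Rescaled matrix whose upper-triangle sum is 1 (within 1e-12).
#' @export
cost_normalize <- function(scan) {
  assert_square_matrix(scan, "scan")
  total <- sum(upper_tri_values(scan))
  if (total <= 0)
    stop("cost normalization undefined: network has no edges", call. = FALSE)
  scan / total
}
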