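# Reproducibility indices: within/between-subject CV, ICC(A,1),
# similarity, and connectivity-binned edge summaries.

check_measure_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric subjects x sessions matrix",
         call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 subjects and 2 sessions", call. = FALSE)
  if (any(!is.finite(values)))
    stop("'values' contains missing or non-finite cells", call. = FALSE)
  invisible(values)
}

#' Within-subject coefficient of variation
#'
#' For each subject, the sample standard deviation across its repeated
#' sessions; `CV_ws` is the mean of these within-subject sds divided by
#' the grand mean, in percent. Scale-invariant (multiplying all values by
#' c > 0 leaves it unchanged) but not shift-invariant, as for any CV.
#'
#' @param values Numeric subjects x sessions matrix (no missing cells).
#' @return CV_ws in percent.
#' @examples
#' cv_within(rbind(c(1, 3), c(1, 3)))  # 70.71
#' @export
cv_within <- function(values) {
  check_measure_table(values)
  gm <- mean(values)
  if (abs(gm) < .Machine$double.eps * 100)
    stop("CV undefined: grand mean is zero", call. = FALSE)
  100 * mean(apply(values, 1, sd)) / gm
}

#' Between-subject coefficient of variation
#'
#' For each session, the sample standard deviation across subjects;
#' `CV_bs` is the mean of these per-session sds divided by the grand
#' mean, in percent.
#'
#' @inheritParams cv_within
#' @return CV_bs in percent.
#' @export
cv_between <- function(values) {
  check_measure_table(values)
  gm <- mean(values)
  if (abs(gm) < .Machine$double.eps * 100)
    stop("CV undefined: grand mean is zero", call. = FALSE)
  100 * mean(apply(values, 2, sd)) / gm
}

#' Two-way absolute-agreement single-measures ICC — ICC(A,1)
#'
#' McGraw & Wong's ICC(A,1): a two-way ANOVA decomposition of the
#' subjects x sessions table with subjects as random rows and sessions
#' as columns,
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`,
#' where `MS_R`, `MS_C`, `MS_E` are the between-subject, between-session
#' and residual mean squares. Estimates may be negative and are reported
#' untruncated.
#'
#' @inheritParams cv_within
#' @return ICC estimate; `NA` when the table has zero total variance
#'   (agreement undefined).
#' @seealso [icc_class()]
#' @export
icc_a1 <- function(values) {
  check_measure_table(values)
  n <- nrow(values)
  k <- ncol(values)
  gm <- mean(values)
  row_m <- rowMeans(values)
  col_m <- colMeans(values)
  ss_total <- sum((values - gm)^2)
  if (ss_total < .Machine$double.eps * 100 * max(1, gm^2))
    return(NA_real_)
  ms_r <- k * sum((row_m - gm)^2) / (n - 1)
  ms_c <- n * sum((col_m - gm)^2) / (k - 1)
  ss_e <- ss_total - k * sum((row_m - gm)^2) - n * sum((col_m - gm)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
}

#' Classify an ICC value
#'
#' Reproducibility classes: poor (< 0.5), moderate (\[0.5, 0.75)), good
#' (\[0.75, 0.9)), excellent (>= 0.9).
#'
#' @param icc Numeric vector of ICC estimates.
#' @return Factor with levels poor/moderate/good/excellent (`NA` kept).
#' @export
icc_class <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
      labels = c("poor", "moderate", "good", "excellent"), right = FALSE)
}

#' Per-edge reproducibility matrices of a test-retest cohort
#'
#' Applies [cv_within()], [cv_between()] and [icc_a1()] independently to
#' every upper-triangle edge's subjects x sessions table (vectorized over
#' edges). Edges whose grand mean is zero across the whole cohort are
#' undefined (`NA`) and counted in the `n_undefined` field.
#'
#' @param cohort A [cohort()]; every subject must have every session.
#' @return Object of class `edge_reliability`: list with symmetric
#'   matrices `mean` (cohort-mean connectivity), `cv_ws`, `cv_bs`, `icc`,
#'   plus `n_undefined`.
#' @export
edge_reliability <- function(cohort) {
  stopifnot(inherits(cohort, "connrep_cohort"))
  a <- cohort_edge_array(cohort)
  S <- dim(a)[1]; K <- dim(a)[2]; E <- dim(a)[3]
  if (S < 2L || K < 2L)
    stop("need at least 2 subjects and 2 sessions", call. = FALSE)
  gm <- apply(a, 3, mean)
  defined <- gm > 0
  sub_m <- apply(a, c(1, 3), mean)              # S x E
  ses_m <- apply(a, c(2, 3), mean)              # K x E
  sd_ws <- sqrt(apply(a, c(1, 3), var))         # sd across sessions
  sd_bs <- sqrt(apply(a, c(2, 3), var))         # sd across subjects
  cv_ws <- ifelse(defined, 100 * colMeans(sd_ws) / gm, NA_real_)
  cv_bs <- ifelse(defined, 100 * colMeans(sd_bs) / gm, NA_real_)
  ss_r <- K * colSums((t(sub_m) - gm)^2 |> t())
  ss_c <- S * colSums((t(ses_m) - gm)^2 |> t())
  ss_tot <- apply(a, 3, function(x) sum((x - mean(x))^2))
  ms_r <- ss_r / (S - 1)
  ms_c <- ss_c / (K - 1)
  ms_e <- (ss_tot - ss_r - ss_c) / ((S - 1) * (K - 1))
  icc <- (ms_r - ms_e) / (ms_r + (K - 1) * ms_e + (K / S) * (ms_c - ms_e))
  icc[ss_tot < .Machine$double.eps * 100] <- NA_real_
  n <- cohort$n_nodes
  lab <- cohort$node_labels
  structure(list(
    mean = matrix_from_upper_tri(gm, n, lab),
    cv_ws = matrix_from_upper_tri(cv_ws, n, lab),
    cv_bs = matrix_from_upper_tri(cv_bs, n, lab),
    icc = matrix_from_upper_tri(icc, n, lab),
    n_undefined = sum(!defined)),
    class = "edge_reliability")
}

#' @export
print.edge_reliability <- function(x, ...) {
  v <- function(m) stats::median(upper_tri_values(m), na.rm = TRUE)
  cat(sprintf(paste0("edge reliability: %d nodes; median CV_ws %.1f%%, ",
                     "CV_bs %.1f%%, ICC %.2f (%d undefined edges)\n"),
              nrow(x$mean), v(x$cv_ws), v(x$cv_bs), v(x$icc),
              x$n_undefined))
  invisible(x)
}

#' Bin edges by mean connectivity and summarize reproducibility per bin
#'
#' Edges are assigned to half-open connectivity bins
#' `[b, b + step)` from `bin_start` to `bin_stop`, plus one overflow bin
#' for values `>= bin_stop` (31 groups at the defaults 0 to 0.3 by 0.01).
#' Per bin, reports the edge count and mean and sd of each supplied
#' reproducibility index. Edges with undefined indices (`NA`, e.g.
#' all-zero edges) are excluded from the index summaries but still
#' counted in `n_edges`.
#'
#' @param mean_matrix Symmetric matrix of cohort-mean connectivity (or an
#'   [edge_reliability()] object, in which case its index matrices are
#'   used).
#' @param index_matrices Named list of symmetric index matrices (ignored
#'   when `mean_matrix` is an `edge_reliability`).
#' @param bin_start,bin_stop,bin_step Bin grid (defaults 0, 0.3, 0.01).
#' @return Data frame with one row per bin: `bin`, `lower`, `upper`,
#'   `n_edges`, and `<index>_mean`, `<index>_sd` columns.
#' @export
bin_edges_by_connectivity <- function(mean_matrix, index_matrices = list(),
                                      bin_start = 0, bin_stop = 0.3,
                                      bin_step = 0.01) {
  assert_scalar_number(bin_step, "bin_step", lower = 0, strict_lower = TRUE)
  if (bin_stop <= bin_start)
    stop("'bin_stop' must exceed 'bin_start'", call. = FALSE)
  if (inherits(mean_matrix, "edge_reliability")) {
    index_matrices <- mean_matrix[c("cv_ws", "cv_bs", "icc")]
    mean_matrix <- mean_matrix$mean
  }
  mv <- upper_tri_values(mean_matrix)
  breaks <- threshold_sweep(bin_start, bin_stop, bin_step)
  lower <- breaks[-length(breaks)]
  n_bins <- length(lower) + 1L              # + overflow group
  idx <- findInterval(mv, c(breaks, Inf), rightmost.closed = FALSE)
  idx[idx < 1L] <- NA                       # below bin_start: excluded
  out <- data.frame(bin = seq_len(n_bins),
                    lower = c(lower, bin_stop),
                    upper = c(lower + bin_step, Inf),
                    n_edges = vapply(seq_len(n_bins),
                                     function(b) sum(idx == b, na.rm = TRUE),
                                     numeric(1)))
  for (nm in names(index_matrices)) {
    iv <- upper_tri_values(index_matrices[[nm]])
    out[[paste0(nm, "_mean")]] <- vapply(seq_len(n_bins), function(b)
      if (any(idx == b & !is.na(iv), na.rm = TRUE))
        mean(iv[which(idx == b)], na.rm = TRUE) else NA_real_, numeric(1))
    out[[paste0(nm, "_sd")]] <- vapply(seq_len(n_bins), function(b)
      if (sum(idx == b & !is.na(iv), na.rm = TRUE) > 1)
        sd(iv[which(idx == b)], na.rm = TRUE) else NA_real_, numeric(1))
    out[[paste0(nm, "_median")]] <- vapply(seq_len(n_bins), function(b)
      if (any(idx == b & !is.na(iv), na.rm = TRUE))
        median(iv[which(idx == b)], na.rm = TRUE) else NA_real_, numeric(1))
  }
  out
}

#' Within- and between-subject similarity of connectivity matrices
#'
#' Within-subject similarity: for each subject, the Pearson correlation
#' between the vectorized upper triangles of its two (or more) sessions
#' (all session pairs averaged), then averaged over subjects.
#' Between-subject similarity: per session, the mean Pearson correlation
#' over all unordered subject pairs, averaged across sessions.
#'
#' @param cohort A [cohort()].
#' @return List with `within_subject` and `between_subject`; `NA` if a
#'   scan's connectivity vector is constant (correlation undefined).
#' @export
similarity <- function(cohort) {
  stopifnot(inherits(cohort, "connrep_cohort"))
  subs <- cohort$subjects
  sess <- cohort$sessions
  vecs <- lapply(subs, function(s)
    vapply(sess,
           function(r) upper_tri_values(cohort$scans[[s]][[r]]),
           numeric(cohort$n_nodes * (cohort$n_nodes - 1) / 2)))
  names(vecs) <- subs
  safe_cor <- function(x, y)
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  within <- mean(vapply(vecs, function(v) {
    pr <- utils::combn(length(sess), 2)
    mean(vapply(seq_len(ncol(pr)),
                function(p) safe_cor(v[, pr[1, p]], v[, pr[2, p]]),
                numeric(1)))
  }, numeric(1)))
  between <- mean(vapply(seq_along(sess), function(ki) {
    pr <- utils::combn(length(subs), 2)
    mean(vapply(seq_len(ncol(pr)), function(p)
      safe_cor(vecs[[pr[1, p]]][, ki], vecs[[pr[2, p]]][, ki]),
      numeric(1)))
  }, numeric(1)))
  list(within_subject = within, between_subject = between)
}
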