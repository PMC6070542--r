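# Sparsity-integrated metric summaries: one number per
# subject/session/metric/normalization, obtained by integrating the
# metric-versus-sparsity curve across the threshold sweep.

#' Integrate a metric-versus-sparsity curve
#'
#' Trapezoidal integral of the metric over sparsity. By default the
#' integral is divided by the sparsity range, giving a sparsity-weighted
#' mean that keeps the metric's own units and stays comparable across
#' subjects whose sparsity ranges differ slightly. Points are sorted by
#' sparsity first; duplicate sparsity values (two thresholds yielding the
#' same mask) are collapsed by averaging the metric.
#'
#' @param sparsity Numeric vector of sparsity values (>= 2 distinct).
#' @param value Metric values at those sparsities.
#' @param normalize Divide by the sparsity range (default `TRUE`);
#'   `FALSE` returns the raw integral.
#' @return The integrated (by default range-normalized) metric.
#' @examples
#' integrate_curve(c(0.1, 0.3), c(1, 3))  # 2
#' @export
integrate_curve <- function(sparsity, value, normalize = TRUE) {
  if (length(sparsity) != length(value))
    stop("'sparsity' and 'value' lengths differ", call. = FALSE)
  if (any(!is.finite(sparsity)) || any(!is.finite(value)))
    stop("curve contains non-finite points", call. = FALSE)
  o <- order(sparsity)
  s <- sparsity[o]; v <- value[o]
  if (anyDuplicated(s)) {
    v <- as.numeric(tapply(v, s, mean))
    s <- sort(unique(s))
  }
  if (length(s) < 2L)
    stop("degenerate curve: all sparsity values are equal", call. = FALSE)
  area <- pracma::trapz(s, v)
  if (normalize) area / (s[length(s)] - s[1]) else area
}

#' Integrated-metric reliability table across a threshold sweep
#'
#' Builds, for every metric x strategy x normalization condition, the
#' per-subject/session metric-versus-sparsity curve from a long table of
#' per-threshold records, integrates each curve with [integrate_curve()],
#' and summarizes the resulting subjects x sessions values with session
#' means and sds, [cv_between()], [cv_within()], [icc_a1()] and the ICC
#' class.
#'
#' @param records Long data frame with columns `subject`, `session`,
#'   `strategy`, `normalized` (logical), `threshold`, `sparsity`, and one
#'   column per metric. Every subject/session must have a record at every
#'   threshold of its stratum; gaps raise an error listing the missing
#'   thresholds.
#' @param metrics Metric column names to summarize (default the four
#'   network metrics present in the table).
#' @param normalize_range Passed to [integrate_curve()] as `normalize`.
#' @return Data frame with one row per strategy x normalization x metric:
#'   per-session `mean_<session>`, `sd_<session>`, `cv_bs`, `cv_ws`,
#'   `icc`, `icc_class`.
#' @export
summarize_cohort <- function(records,
                             metrics = intersect(c("E_glob", "E_loc",
                                                   "C_w", "L_w"),
                                                 names(records)),
                             normalize_range = TRUE) {
  req <- c("subject", "session", "strategy", "normalized", "threshold",
           "sparsity", metrics)
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (strat in unique(records$strategy)) {
    for (norm in unique(records$normalized)) {
      sub <- records[records$strategy == strat &
                       records$normalized == norm, ]
      all_thr <- sort(unique(sub$threshold))
      cells <- split(sub, list(sub$subject, sub$session), drop = TRUE)
      gaps <- lapply(cells, function(df)
        setdiff(all_thr, df$threshold))
      bad <- vapply(gaps, length, integer(1)) > 0
      if (any(bad))
        stop("missing thresholds for ",
             paste(sprintf("%s (%s)", names(gaps)[bad],
                           vapply(gaps[bad], function(g)
                             paste(signif(g, 6), collapse = ","),
                             character(1))), collapse = "; "),
             call. = FALSE)
      subjects <- sort(unique(sub$subject))
      sessions <- sort(unique(sub$session))
      for (metric in metrics) {
        vals <- matrix(NA_real_, length(subjects), length(sessions),
                       dimnames = list(subjects, sessions))
        for (s in subjects) for (r in sessions) {
          df <- sub[sub$subject == s & sub$session == r, ]
          vals[s, r] <- integrate_curve(df$sparsity, df[[metric]],
                                        normalize = normalize_range)
        }
        icc <- icc_a1(vals)
        row <- data.frame(strategy = strat, normalized = norm,
                          metric = metric, stringsAsFactors = FALSE)
        for (r in sessions) {
          row[[paste0("mean_", r)]] <- mean(vals[, r])
          row[[paste0("sd_", r)]] <- sd(vals[, r])
        }
        row$cv_bs <- cv_between(vals)
        row$cv_ws <- cv_within(vals)
        row$icc <- icc
        row$icc_class <- as.character(icc_class(icc))
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}
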