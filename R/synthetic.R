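#' Configuration for the synthetic test-retest connectome generator
#'
#' The generator emulates a short-term test-retest study of
#' probabilistic-tractography connectomes: a cohort of subjects, each
#' scanned in two back-to-back sessions, yielding one symmetric
#' connectivity-probability matrix per scan. Connectivity decays
#' exponentially with the Euclidean distance between (abstract) node
#' positions, so that short-range edges are strong and the bulk of the
#' edge distribution sits below 0.01, as observed in probabilistic
#' tractography at a 78-region cortical parcellation.
#'
#' Edge values follow a two-level lognormal variance-components model:
#' a population template `T_ij`, a per-subject multiplicative effect with
#' log-scale standard deviation `sigma_between`, and a per-session effect
#' with log-scale standard deviation `sigma_within`. Both sds are scaled
#' per edge by `(median(T)/T_ij)^noise_scaling` (clamped to \[0.2, 5\]),
#' making weak edges noisier than strong ones — the dominant empirical
#' feature of tractography connectivity, where weak edges derive from few
#' streamlines. Because the scaling equals 1 at the median template edge,
#' the median per-edge reliability indices still match the homogeneous
#' closed forms of [theoretical_reliability()], and the within/between
#' variance ratio (hence ICC) is the same for every edge.
#'
#' @param n_nodes Number of network nodes (default 78, a cortical
#'   AAL-style parcellation).
#' @param n_subjects Number of subjects (default 30).
#' @param n_sessions Number of repeated sessions per subject (default 2).
#' @param decay_rate Exponential fall-off of connectivity with inter-node
#'   distance (unit-cube distance units; default 9).
#' @param base_scale Template connectivity at zero distance (default 0.5).
#'   The defaults place about 80% of edges below connectivity 0.01.
#' @param sigma_between Between-subject log-scale sd (default 0.3).
#' @param sigma_within Within-subject (session) log-scale sd (default 0.1);
#'   smaller than `sigma_between`, as in test-retest data.
#' @param noise_scaling Exponent linking edge strength to noise magnitude
#'   (default 0.3); 0 gives homogeneous noise on the log scale.
#' @param clip_max Ceiling applied to connectivity values (default 1,
#'   probabilities). Heavy clipping (large `base_scale`) breaks the
#'   lognormal closed forms.
#' @param seed Integer RNG seed (default 42).
#' @return A validated list of class `synthetic_config`.
#' @seealso [generate_cohort()], [theoretical_reliability()]
#' @export
synthetic_config <- function(n_nodes = 78L, n_subjects = 30L,
                             n_sessions = 2L, decay_rate = 9,
                             base_scale = 0.5, sigma_between = 0.3,
                             sigma_within = 0.1, noise_scaling = 0.3,
                             clip_max = 1, seed = 42L) {
  cfg <- list(n_nodes = assert_count(n_nodes, "n_nodes", min = 3L),
              n_subjects = assert_count(n_subjects, "n_subjects", min = 2L),
              n_sessions = assert_count(n_sessions, "n_sessions", min = 2L),
              decay_rate = assert_scalar_number(decay_rate, "decay_rate",
                                                lower = 0,
                                                strict_lower = TRUE),
              base_scale = assert_scalar_number(base_scale, "base_scale",
                                                lower = 0,
                                                strict_lower = TRUE),
              sigma_between = assert_scalar_number(sigma_between,
                                                   "sigma_between",
                                                   lower = 0),
              sigma_within = assert_scalar_number(sigma_within,
                                                  "sigma_within", lower = 0),
              noise_scaling = assert_scalar_number(noise_scaling,
                                                   "noise_scaling",
                                                   lower = 0),
              clip_max = assert_scalar_number(clip_max, "clip_max", lower = 0,
                                              upper = 1,
                                              strict_lower = TRUE),
              seed = assert_count(seed, "seed", min = 0L))
  class(cfg) <- "synthetic_config"
  cfg
}

# Clamp bounds for the per-edge noise-scaling factor.
NOISE_SCALE_MIN <- 0.2
NOISE_SCALE_MAX <- 5

# Template connectivity and per-edge noise scale for a config
# (deterministic given the seed; node positions use a dedicated substream).
synthetic_template <- function(config) {
  with_preserved_seed(config$seed, {
    pos <- matrix(runif(config$n_nodes * 3), config$n_nodes, 3)
    d <- as.matrix(dist(pos))
    template <- config$base_scale * exp(-config$decay_rate * d)
    diag(template) <- 0
    tv <- upper_tri_values(template)
    gv <- pmin(NOISE_SCALE_MAX,
               pmax(NOISE_SCALE_MIN,
                    (median(tv) / tv)^config$noise_scaling))
    list(template = tv, noise_scale = gv, positions = pos)
  })
}

#' Generate a synthetic test-retest cohort
#'
#' Deterministic given `config$seed`. Node positions are placed uniformly
#' in the unit cube; the population template is
#' `T_ij = base_scale * exp(-decay_rate * dist(i, j))`; each subject draws
#' a lognormal multiplicative effect per edge
#' (`log`-sd `sigma_between * g_ij`), each session a further effect
#' (`log`-sd `sigma_within * g_ij`), where `g_ij` is the edge's noise
#' scale (see [synthetic_config()]); values are clipped at `clip_max`.
#' Only the upper triangle is drawn, so matrices are symmetric with a
#' zero diagonal by construction.
#'
#' @param config A [synthetic_config()].
#' @return A [cohort()] with subjects `s01, s02, ...` and sessions
#'   `1, 2, ...`.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_nodes = 10, n_subjects = 3))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  tpl <- synthetic_template(config)
  n <- config$n_nodes
  E <- n * (n - 1) / 2
  labels <- sprintf("n%03d", seq_len(n))
  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  sessions <- as.character(seq_len(config$n_sessions))
  scans <- with_preserved_seed(config$seed + 1L, {
    out <- list()
    for (s in subjects) {
      b <- rnorm(E, 0, 1) * config$sigma_between * tpl$noise_scale
      subj <- tpl$template * exp(b)
      out[[s]] <- list()
      for (r in sessions) {
        e <- rnorm(E, 0, 1) * config$sigma_within * tpl$noise_scale
        p <- pmin(config$clip_max, subj * exp(e))
        out[[s]][[r]] <- matrix_from_upper_tri(p, n, labels)
      }
    }
    out
  })
  cohort(scans, node_labels = labels)
}

#' Closed-form reliability expectations for the synthetic model
#'
#' Small-noise lognormal approximations for the two-level
#' variance-components model of [generate_cohort()], used as the oracle
#' in parameter-recovery checks. For a lognormal variable with log-scale
#' sd `s`, the coefficient of variation is `sqrt(exp(s^2) - 1)`. The
#' between-subject CV uses the total log-variance
#' `sigma_between^2 + sigma_within^2` (a single session mixes both
#' levels), and the expected intraclass correlation is the log-scale
#' variance ratio `sigma_between^2 / (sigma_between^2 + sigma_within^2)`.
#'
#' The approximations hold for log-sds up to about 0.5 and negligible
#' clipping (`base_scale` well below `clip_max`). They describe population
#' quantities; finite-sample estimators are biased low — most notably, a
#' standard deviation estimated from k sessions has expectation
#' `c4(k) = sqrt(2/(k-1)) * gamma(k/2) / gamma((k-1)/2)` times the true
#' sd, which is about 0.80 for k = 2.
#'
#' @param config A [synthetic_config()].
#' @return A list with `expected_cv_within` and `expected_cv_between`
#'   (percent) and `expected_icc`.
#' @examples
#' theoretical_reliability(synthetic_config(sigma_within = 0.1))
#' @export
theoretical_reliability <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  sw2 <- config$sigma_within^2
  sb2 <- config$sigma_between^2
  tot <- sw2 + sb2
  list(expected_cv_within = 100 * sqrt(exp(sw2) - 1),
       expected_cv_between = 100 * sqrt(exp(tot) - 1),
       expected_icc = if (tot == 0) NA_real_ else sb2 / tot)
}
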