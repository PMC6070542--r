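# Cohort-mean connectivity per edge, computed directly from the scans.
cohort_mean_matrix <- function(coh) {
  acc <- 0
  n <- 0
  for (s in coh$subjects)
    for (r in coh$sessions) {
      acc <- acc + coh$scans[[s]][[r]]
      n <- n + 1
    }
  acc / n
}

test_that("generated cohorts satisfy the matrix invariants for any seed", {
  for (seed in c(3, 11, 2026)) {
    coh <- small_cohort(seed = seed, n_nodes = 12, n_subjects = 3)
    for (s in coh$subjects) {
      expect_identical(sort(names(coh$scans[[s]])), coh$sessions)
      for (r in coh$sessions) {
        m <- coh$scans[[s]][[r]]
        expect_identical(m, t(m))
        expect_true(all(diag(m) == 0))
        expect_true(all(m >= 0 & m <= 1))
      }
    }
  }
})

test_that("same seed gives bit-identical cohorts, different seeds differ", {
  a <- small_cohort(seed = 5)
  b <- small_cohort(seed = 5)
  c <- small_cohort(seed = 6)
  expect_identical(a$scans, b$scans)
  expect_false(identical(a$scans, c$scans))
})

test_that("zero session noise makes repeated sessions identical", {
  coh <- small_cohort(seed = 2, sigma_within = 0)
  for (s in coh$subjects)
    expect_identical(coh$scans[[s]][["1"]], coh$scans[[s]][["2"]])
})

test_that("fully degenerate model collapses to one shared template", {
  coh <- small_cohort(seed = 2, sigma_within = 0, sigma_between = 0)
  ref <- coh$scans[[1]][[1]]
  for (s in coh$subjects)
    for (r in coh$sessions)
      expect_identical(coh$scans[[s]][[r]], ref)
  expect_true(max(ref) <= 1)
})

test_that("default study design puts ~80% of edges below connectivity 0.01", {
  for (seed in c(42, 7)) {
    coh <- generate_cohort(synthetic_config(seed = seed))
    gm <- cohort_mean_matrix(coh)
    frac <- mean(gm[upper.tri(gm)] < 0.01)
    expect_gt(frac, 0.75)
    expect_lt(frac, 0.87)
  }
})

test_that("invalid generator configurations name the offending field", {
  expect_error(synthetic_config(n_nodes = 2), "n_nodes")
  expect_error(synthetic_config(n_subjects = 1), "n_subjects")
  expect_error(synthetic_config(sigma_within = -0.1), "sigma_within")
  expect_error(synthetic_config(decay_rate = 0), "decay_rate")
  expect_error(synthetic_config(clip_max = 1.5), "clip_max")
})

test_that("closed-form reliability oracle matches its stated values", {
  th <- theoretical_reliability(synthetic_config(sigma_within = 0.1))
  expect_equal(th$expected_cv_within, 100 * sqrt(exp(0.01) - 1),
               tolerance = 1e-12)
  expect_equal(th$expected_cv_within, 10.025, tolerance = 1e-4)

  th0 <- theoretical_reliability(synthetic_config(sigma_within = 0))
  expect_identical(th0$expected_cv_within, 0)
  expect_identical(th0$expected_icc, 1)

  thEq <- theoretical_reliability(synthetic_config(sigma_within = 0.2,
                                                   sigma_between = 0.2))
  expect_equal(thEq$expected_icc, 0.5)
})

test_that("raising session noise does not lower the median edge CV_ws", {
  meds <- vapply(c(0.05, 0.1, 0.2), function(sw) {
    er <- edge_reliability(small_cohort(seed = 9, n_nodes = 20,
                                        n_subjects = 8, sigma_within = sw))
    median(er$cv_ws[upper.tri(er$cv_ws)], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("cohort round-trips through the on-disk text layout", {
  coh <- small_cohort(seed = 4, n_nodes = 8, n_subjects = 3)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "sub-s01", "ses-1.tsv")))
  back <- read_cohort(dir)
  expect_identical(back$subjects, coh$subjects)
  expect_identical(back$node_labels, coh$node_labels)
  for (s in coh$subjects)
    for (r in coh$sessions)
      expect_equal(back$scans[[s]][[r]], coh$scans[[s]][[r]],
                   tolerance = 1e-10)
})
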