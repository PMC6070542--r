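test_that("symmetrize averages the two directed probabilities", {
  fw <- matrix(0, 3, 3)
  bw <- matrix(0, 3, 3)
  fw[1, 2] <- 0.2
  bw[2, 1] <- 0.4
  out <- symmetrize(fw, bw)
  expect_equal(out[1, 2], 0.3)
  expect_equal(out[2, 1], 0.3)
  expect_true(all(diag(out) == 0))

  # already-consistent directed input comes back unchanged (diag zeroed)
  set.seed(1)
  p <- rand_weight_matrix(4, density = 1, wmin = 0, wmax = 0.5)
  diag(p) <- runif(4, 0, 0.5)
  q <- p
  diag(q) <- 0
  expect_equal(symmetrize(p, t(p)), q)
  expect_equal(symmetrize(matrix(0, 3, 3), matrix(0, 3, 3)),
               matrix(0, 3, 3))
  expect_error(symmetrize(matrix(0, 3, 3), matrix(0, 4, 4)), "dimension")
})

test_that("group threshold rule is mean + 2 sample sd, strict inequality", {
  base <- matrix(0, 4, 4)
  mk_scan <- function(p) {
    m <- base
    m[1, 2] <- m[2, 1] <- p
    m
  }
  # zero variance: 0.05 + 0 < 0.0575 -> removed
  scans <- rep(list(mk_scan(0.05)), 3)
  mask <- group_threshold_mask(scans, 0.0575, "common")
  expect_false(mask$mask[1, 2])
  # same scans, lower threshold -> retained
  expect_true(group_threshold_mask(scans, 0.04, "common")$mask[1, 2])
  # tie (mean + 2 sd == threshold) retains the edge
  expect_true(group_threshold_mask(scans, 0.05, "common")$mask[1, 2])

  # four scans, hand-computed mean/sd: mean 0.025, sd 0.0129099
  scans4 <- lapply(c(0.01, 0.02, 0.03, 0.04), mk_scan)
  stat <- mean(c(0.01, 0.02, 0.03, 0.04)) + 2 * sd(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(stat, 0.0508199, tolerance = 1e-6)
  expect_true(group_threshold_mask(scans4, 0.05, "common")$mask[1, 2])
  expect_false(group_threshold_mask(scans4, 0.0509, "common")$mask[1, 2])

  expect_error(group_threshold_mask(scans4[1], 0.05, "common"),
               "at least 2")
})

test_that("common strategy yields one shared mask, separate one per session", {
  coh <- small_cohort(seed = 3, n_nodes = 20, n_subjects = 6)
  com <- group_threshold_mask(coh, 0.02, "common")
  expect_s3_class(com, "connrep_edge_mask")
  sep <- group_threshold_mask(coh, 0.02, "separate")
  expect_named(sep, coh$sessions)
  # separate masks are close to the common one on test-retest data
  expect_lt(abs(sparsity(sep[["1"]]) - sparsity(com)), 0.05)
  expect_lt(abs(sparsity(sep[["2"]]) - sparsity(com)), 0.05)
})

test_that("threshold sweep is inclusive with tolerant endpoint handling", {
  s <- threshold_sweep(0.01, 0.10, 0.0025)
  expect_length(s, 37)
  expect_equal(s[1], 0.01)
  expect_equal(s[37], 0.10)
  expect_identical(threshold_sweep(0.01, 0.01, 0.0025), 0.01)
  expect_length(threshold_sweep(0, 0.3, 0.01), 31)
  # endpoint not a multiple of step -> excluded
  expect_equal(max(threshold_sweep(0, 0.095, 0.01)), 0.09)
  expect_error(threshold_sweep(0.01, 0.1, 0), "step")
})

test_that("sparsity counts retained upper-triangle edges", {
  full <- matrix(TRUE, 78, 78)
  diag(full) <- FALSE
  expect_equal(sparsity(full), 1)
  expect_equal(sum(upper.tri(full)), 3003)
  expect_equal(sparsity(matrix(FALSE, 10, 10)), 0)
  m4 <- matrix(FALSE, 4, 4)
  m4[1, 2] <- m4[2, 1] <- m4[1, 3] <- m4[3, 1] <- m4[3, 4] <- m4[4, 3] <- TRUE
  expect_equal(sparsity(m4), 0.5)
})

test_that("apply_mask zeroes excluded edges and is idempotent", {
  set.seed(8)
  W <- rand_weight_matrix(6)
  full <- matrix(TRUE, 6, 6)
  expect_equal(apply_mask(W, full), W)
  expect_equal(apply_mask(W, !full), matrix(0, 6, 6))
  one <- matrix(FALSE, 6, 6)
  one[1, 2] <- one[2, 1] <- TRUE
  masked <- apply_mask(W, one)
  expect_equal(sum(masked != 0), 2)
  expect_identical(masked, t(masked))
  expect_equal(apply_mask(masked, one), masked)
  expect_error(apply_mask(W, matrix(TRUE, 5, 5)), "dimension")
})

test_that("cost normalization scales the upper-triangle sum to one", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.4
  expect_equal(cost_normalize(m)[1, 2], 1)
  m[3, 4] <- m[4, 3] <- 0.3
  m[1, 2] <- m[2, 1] <- 0.1
  cn <- cost_normalize(m)
  expect_equal(cn[1, 2], 0.25)
  expect_equal(cn[3, 4], 0.75)
  set.seed(2)
  W <- rand_weight_matrix(8)
  expect_equal(sum(cost_normalize(W)[upper.tri(W)]), 1, tolerance = 1e-12)
  # already unit-cost networks are fixed points
  expect_equal(cost_normalize(cost_normalize(W)), cost_normalize(W),
               tolerance = 1e-12)
  expect_error(cost_normalize(matrix(0, 3, 3)), "no edges")
})

test_that("raising the threshold never adds edges (sparsity monotone)", {
  coh <- small_cohort(seed = 12, n_nodes = 24, n_subjects = 6)
  thr <- threshold_sweep(0.01, 0.1, 0.01)
  masks <- lapply(thr, function(t) group_threshold_mask(coh, t, "common"))
  sp <- vapply(masks, sparsity, numeric(1))
  expect_true(all(diff(sp) <= 0))
  for (i in seq_len(length(masks) - 1)) {
    gained <- masks[[i + 1]]$mask & !masks[[i]]$mask
    expect_false(any(gained))
  }
})
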