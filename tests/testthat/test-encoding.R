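test_that("canonical HRF has the expected double-gamma shape", {
  h <- canonical_hrf(0.1)
  peak_t <- (which.max(h) - 1) * 0.1
  expect_lt(abs(peak_t - 5), 0.5)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # negative undershoot lobe after the peak
  expect_lt(min(h[(which.max(h) + 1):length(h)]), 0)
  expect_error(canonical_hrf(0), class = "sc_parameter_error")
})

test_that("feature regressors are linear and match a direct convolution oracle", {
  clips <- tibble::tibble(item_id = "c1", onset = 10, duration = 10)
  sched <- stimulus_schedule(clips, tr = 2.6, n_volumes = 467)

  zero <- build_feature_regressor(sched, c(c1 = 0))
  expect_equal(zero, rep(0, 467))

  r1 <- build_feature_regressor(sched, c(c1 = 3))
  r2 <- build_feature_regressor(sched, c(c1 = 6))
  expect_equal(r2, 2 * r1, tolerance = 1e-12)

  # independent direct convolution at microtime resolution
  mt <- 16L
  dt <- 2.6 / mt
  grid <- numeric(467 * mt)
  from <- floor(10 / dt) + 1
  to <- ceiling(20 / dt)
  grid[from:to] <- 3
  kern <- canonical_hrf(dt)
  conv <- oracle_convolve(grid, kern)
  want <- conv[(seq_len(467) - 1) * mt + 1]
  want <- want - mean(want)
  expect_equal(r1, want, tolerance = 1e-8)

  expect_error(build_feature_regressor(sched, c(other = 1)),
               class = "sc_coverage_error")
})

test_that("first-level betas equal closed-form simple regression", {
  set.seed(20)
  x <- rnorm(100)
  y <- 3 * x + 7
  expect_equal(first_level_betas(matrix(y, 1), x), 3, tolerance = 1e-10)

  # orthogonal signal
  x0 <- rep(c(-1, 1), 50)
  y0 <- rep(c(1, 1), 50)
  expect_lt(abs(first_level_betas(matrix(y0, 1), x0)), 1e-10)

  bold <- matrix(rnorm(500), 5, 100)
  got <- first_level_betas(bold, x)
  for (v in 1:5) {
    expect_equal(got[v], cov(bold[v, ], x) / var(x), tolerance = 1e-10)
    fit <- lm(bold[v, ] ~ x)
    expect_equal(got[v], unname(coef(fit)["x"]), tolerance = 1e-10)
  }
  expect_error(first_level_betas(bold, rep(1, 100)),
               class = "sc_parameter_error")
})

test_that("group one-sample t matches hand computation and flags zero variance", {
  res <- group_one_sample_t(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(res$t[1], 2 / (1 / sqrt(3)))
  expect_equal(res$p[1], pt(res$t[1], df = 2, lower.tail = FALSE))

  sym <- group_one_sample_t(matrix(c(-2, -1, 1, 2), ncol = 1))
  expect_equal(sym$t[1], 0)
  expect_equal(sym$p[1], 0.5)

  zv <- group_one_sample_t(matrix(c(1, 1, 1), ncol = 1))
  expect_true(is.na(zv$t[1]))
  expect_equal(zv$n_flagged, 1L)

  # cross-check against t.test on random data
  set.seed(21)
  b <- matrix(rnorm(40), 8, 5)
  got <- group_one_sample_t(b)
  for (v in 1:5) {
    tt <- t.test(b[, v], alternative = "greater")
    expect_equal(got$t[v], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(got$p[v], tt$p.value, tolerance = 1e-12)
  }
})

test_that("thresholding implements uncorrected and Bonferroni rules", {
  p <- c(0.0005, 0.002, 0.2)
  expect_equal(threshold_map(p, 0.001, "none"), c(TRUE, FALSE, FALSE))
  expect_true(all(threshold_map(p, 0.999, "none")))

  pv <- runif(1000)
  bon <- threshold_map(pv, 0.05, "bonferroni_fwe")
  expect_identical(bon, pv < 0.05 / 1000)

  # FWE set nested in the uncorrected set when cutoffs order correctly
  unc <- threshold_map(pv, 0.001, "none")
  expect_true(all(!bon | unc))
  expect_error(threshold_map(p, 1.5, "none"), class = "sc_parameter_error")
})

test_that("predictive values count the confusion table correctly", {
  test_map <- c(rep(TRUE, 4), rep(FALSE, 6))
  ref_map <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  res <- ppv_npv(test_map, ref_map)
  expect_equal(res$ppv, 0.75)
  expect_equal(res$npv, 5 / 6)
  expect_equal(c(res$tp, res$fp, res$tn, res$fn), c(3, 1, 5, 1))

  same <- ppv_npv(ref_map, ref_map)
  expect_equal(c(same$ppv, same$npv), c(1, 1))

  none <- ppv_npv(rep(FALSE, 10), ref_map)
  expect_true(is.na(none$ppv))
  expect_match(none$flag, "no_test_positives")
  expect_equal(none$npv, 6 / 10)
})

test_that("cumulative map counts passing features and conserves totals", {
  b1 <- c(TRUE, FALSE, TRUE)
  b2 <- c(TRUE, FALSE, FALSE)
  b3 <- c(TRUE, FALSE, TRUE)
  cm <- cumulative_map(cbind(b1, b2, b3))
  expect_equal(cm, c(3L, 0L, 2L))
  expect_equal(sum(cm), sum(b1) + sum(b2) + sum(b3))
  expect_equal(cumulative_map(cbind(rep(FALSE, 3))), rep(0L, 3))
})

test_that("spatial correlation behaves like pearson over the mask", {
  m <- rnorm(50)
  expect_equal(spatial_correlation(m, m)$r, 1)
  expect_equal(spatial_correlation(m, -m)$r, -1)
  expect_identical(spatial_correlation(rep(1, 50), m)$flag, "constant_input")
})

test_that("spatial similarity of replicate group maps rises as noise falls", {
  sched <- simulate_schedule(n_clips = 12, n_volumes = 150, seed = 30)
  vals <- matrix(runif(24, 0, 10), 12, 2,
                 dimnames = list(sched$clips$item_id, c("f1", "f2")))
  rs <- vapply(c(8, 2, 0.5), function(ns) {
    # one ground truth, two disjoint subject groups = independent noise
    s <- simulate_bold(sched, vals, n_subjects = 12, n_voxels = 200,
                       tuned_fraction = 0.2, noise_sd = ns, seed = 31)
    f1 <- fit_encoding(s$bold[1:6], s$design)
    f2 <- fit_encoding(s$bold[7:12], s$design)
    spatial_correlation(f1$group_beta[, 1], f2$group_beta[, 1])$r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("BOLD matrices and maps round-trip through NIfTI files", {
  skip_if_not_installed("RNifti")
  bold <- matrix(rnorm(4 * 3 * 2 * 10), nrow = 24, ncol = 10)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_bold_nifti(bold, path, dim3d = c(4, 3, 2), tr = 2.6)
  back <- read_bold_nifti(path)
  expect_equal(unname(back[, ]), bold, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(attr(back, "dim3d"), c(4L, 3L, 2L))

  m <- rnorm(24)
  p2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_map_nifti(m, p2, dim3d = c(4, 3, 2))
  arr <- as.array(RNifti::readNifti(p2))
  expect_equal(as.numeric(arr), m, tolerance = 1e-6)
  expect_error(write_map_nifti(m, p2, dim3d = c(5, 3, 2)),
               class = "sc_parameter_error")
})
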