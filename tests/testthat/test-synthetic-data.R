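test_that("generators are deterministic given a seed", {
  a <- simulate_rating_panel(n_items = 20, n_features = 5, n_raters = 4, seed = 3)
  b <- simulate_rating_panel(n_items = 20, n_features = 5, n_raters = 4, seed = 3)
  expect_identical(a$panel$ratings, b$panel$ratings)
  expect_identical(a$truth$true_intensity, b$truth$true_intensity)

  m1 <- simulate_machine_ratings(a$truth, fail_rate = 0.1, seed = 5)
  m2 <- simulate_machine_ratings(b$truth, fail_rate = 0.1, seed = 5)
  expect_identical(m1$ratings, m2$ratings)

  s1 <- simulate_schedule(n_clips = 10, n_volumes = 100, seed = 2)
  bo1 <- simulate_bold(s1, mean_over_raters(a$panel)$values[1:10, ],
                       n_subjects = 2, n_voxels = 30, seed = 4)
  bo2 <- simulate_bold(s1, mean_over_raters(b$panel)$values[1:10, ],
                       n_subjects = 2, n_voxels = 30, seed = 4)
  expect_identical(bo1$bold, bo2$bold)
})

test_that("generator respects scales, profile bounds, and masks", {
  sim <- simulate_rating_panel(n_items = 30, n_features = 8, n_raters = 5,
                               consistency_profile = 0.5, seed = 17)
  expect_true(all(sim$panel$ratings >= 0 & sim$panel$ratings <= 10))
  expect_true(all(sim$truth$true_intensity >= 0 &
                    sim$truth$true_intensity <= 10))
  expect_error(
    simulate_rating_panel(n_items = 5, n_features = 2, n_raters = 3,
                          consistency_profile = 1.2, seed = 1),
    class = "sc_parameter_error"
  )
  mac <- simulate_machine_ratings(sim$truth, seed = 2)
  expect_true(all(mac$ratings >= 0 & mac$ratings <= 10, na.rm = TRUE))
  expect_error(simulate_machine_ratings(sim$truth, floor_bias = 1, seed = 1),
               class = "sc_parameter_error")
})

test_that("noiseless raters are identical with consistency exactly 1", {
  sim <- simulate_rating_panel(n_items = 25, n_features = 3, n_raters = 4,
                               seed = 31)
  truth0 <- sim$truth
  truth0$rater_noise_sd <- rep(0, 3)
  p0 <- resample_rating_panel(truth0, n_raters = 4, seed = 32)
  expect_equal(p0$ratings[, , 1], p0$ratings[, , 4])
  expect_equal(intersubject_consistency(p0)$consistency, rep(1, 3))
})

test_that("noise calibration hits the target consistency on average", {
  # Monte-Carlo check of the noise-sd-to-reliability map at profile 0.6
  reps <- 10
  means <- vapply(seq_len(reps), function(i) {
    sim <- simulate_rating_panel(n_items = 200, n_features = 20,
                                 n_raters = 10, consistency_profile = 0.6,
                                 seed = 100 + i)
    mean(intersubject_consistency(sim$panel)$consistency)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.6), 0.05)
})

test_that("increasing rater noise strictly decreases expected consistency", {
  sim <- simulate_rating_panel(n_items = 300, n_features = 10, n_raters = 10,
                               consistency_profile = 0.9, seed = 41)
  base_sd <- sim$truth$rater_noise_sd
  cons <- vapply(c(0.5, 1, 2, 4), function(mult) {
    truth <- sim$truth
    truth$rater_noise_sd <- base_sd * mult
    p <- resample_rating_panel(truth, n_raters = 10, seed = 42)
    mean(intersubject_consistency(p)$consistency)
  }, numeric(1))
  expect_true(all(diff(cons) < 0))
})

test_that("floor bias is the stated piecewise map and only affects low ratings", {
  expect_equal(floor_biased(4, 0.5), 2)
  expect_equal(floor_biased(6, 0.5), 6)
  expect_equal(floor_biased(c(0, 4.99, 5, 10), 0), c(0, 4.99, 5, 10))
  x <- seq(0, 10, by = 0.25)
  y <- floor_biased(x, 0.3)
  expect_true(all(y[x < 5] < x[x < 5] | x[x < 5] == 0))
  expect_identical(y[x >= 5], x[x >= 5])
})

test_that("a faithful machine reproduces the truth exactly", {
  sim <- simulate_rating_panel(n_items = 40, n_features = 4, n_raters = 3,
                               seed = 51)
  mac <- simulate_machine_ratings(sim$truth, n_rounds = 5,
                                  round_noise_sd = 0, floor_bias = 0,
                                  fail_rate = 0, seed = 52)
  mm <- mean_over_rounds(mac)
  expect_equal(mm$values, sim$truth$true_intensity)
})

test_that("failure rate produces all-round-missing items at the binomial rate", {
  sim <- simulate_rating_panel(n_items = 400, n_features = 3, n_raters = 3,
                               seed = 61)
  mac <- simulate_machine_ratings(sim$truth, fail_rate = 0.05, seed = 62)
  n_failed <- length(mac$failed_items)
  # ~Binomial(400, 0.05): mean 20, sd ~4.4
  expect_gt(n_failed, 5)
  expect_lt(n_failed, 40)
  for (it in mac$failed_items) {
    expect_true(all(is.na(mac$ratings[it, , ])))
  }
})

test_that("synthetic BOLD recovers a planted beta exactly without noise", {
  sched <- simulate_schedule(n_clips = 8, n_volumes = 80, seed = 71)
  vals <- matrix(runif(8, 0, 10), 8, 1,
                 dimnames = list(sched$clips$item_id, "f1"))
  reg <- build_feature_regressor(sched, setNames(vals[, 1], rownames(vals)))
  bold <- matrix(3 * reg, nrow = 1, byrow = TRUE)
  expect_equal(first_level_betas(bold, reg), 3, tolerance = 1e-8)
})

test_that("group t-maps are calibrated under the all-null BOLD model", {
  sched <- simulate_schedule(n_clips = 10, n_volumes = 120, seed = 81)
  vals <- matrix(runif(10, 0, 10), 10, 1,
                 dimnames = list(sched$clips$item_id, "f1"))
  sim <- simulate_bold(sched, vals, n_subjects = 20, n_voxels = 500,
                       tuned_fraction = 0, noise_sd = 1, seed = 82)
  fit <- fit_encoding(sim$bold, sim$design)
  expect_true(all(sim$truth$true_beta == 0))
  fpr05 <- mean(fit$p[, 1] < 0.05)
  expect_lt(abs(fpr05 - 0.05), 0.03)
})

test_that("schedule overrun raises a timing error", {
  expect_error(
    simulate_schedule(n_clips = 50, n_volumes = 20, duration_range = c(10, 12),
                      seed = 1),
    class = "sc_timing_error"
  )
})
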