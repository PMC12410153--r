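test_that("pearson_r matches direct evaluation and flags degenerate input", {
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  x <- rnorm(10)
  expect_equal(pearson_r(x, x)$r, 1.0)
  expect_equal(pearson_r(x, -x)$r, -1.0)
  expect_identical(pearson_r(c(1, 1, 1, 1), rnorm(4))$flag, "constant_input")
  expect_identical(pearson_r(c(1, 2, NA, NA), c(1, 2, 3, 4))$flag,
                   "insufficient_pairs")
})

test_that("feature agreement is 1 for identical matrices and flags constants", {
  p <- rand_panel(10, 4, 3, seed = 1)
  m <- mean_over_raters(p)
  agr <- feature_agreement(m, m)
  expect_equal(agr$agreement, rep(1, 4))

  m2 <- m
  m2$values[, 2] <- 5
  agr2 <- feature_agreement(m2, m)
  expect_identical(agr2$flag[2], "constant_input")
  expect_true(is.na(agr2$agreement[2]))
})

test_that("intersubject consistency equals the brute-force leave-one-out oracle", {
  for (seed in 1:4) {
    p <- rand_panel(5, 3, if (seed %% 2) 3L else 6L, seed = seed,
                    miss_rate = if (seed > 2) 0.15 else 0)
    got <- intersubject_consistency(p)
    want <- oracle_loo_consistency(p$ratings)
    expect_equal(got$consistency, want, tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("identical raters give consistency 1; independent raters hover near 0", {
  arr <- array(rep(runif(20, 0, 10), 3), dim = c(20, 1, 3))
  p <- make_panel(arr)
  expect_equal(intersubject_consistency(p)$consistency, 1.0)

  p0 <- rand_panel(500, 1, 6, seed = 9)
  expect_lt(abs(intersubject_consistency(p0)$consistency), 0.05)
})

test_that("group consistency enumerates C(10,5)/2 = 126 splits and matches the oracle", {
  expect_length(rater_splits(10, 5), 126L)
  expect_length(rater_splits(4, 2), 3L)
  expect_error(rater_splits(9, 5), class = "sc_parameter_error")

  p <- rand_panel(5, 2, 6, seed = 5, miss_rate = 0.1)
  got <- group_consistency(p, group_size = 2)
  want <- oracle_group_consistency(p$ratings, 2)
  expect_equal(got$consistency, want, tolerance = 1e-12)
})

test_that("degenerate split of two raters reduces to their correlation", {
  p <- rand_panel(12, 3, 2, seed = 8)
  got <- group_consistency(p, group_size = 1)
  for (f in 1:3) {
    expect_equal(got$consistency[f],
                 oracle_pearson(p$ratings[, f, 1], p$ratings[, f, 2]))
  }
})

test_that("group consistency is invariant to rater relabeling", {
  p <- rand_panel(10, 3, 6, seed = 11)
  perm <- c(4, 1, 6, 2, 5, 3)
  q <- p
  q$ratings <- p$ratings[, , perm]
  dimnames(q$ratings)[[3]] <- dimnames(p$ratings)[[3]]
  expect_equal(group_consistency(p, 3)$consistency,
               group_consistency(q, 3)$consistency, tolerance = 1e-12)
})

test_that("agreement statistics are invariant under common affine rescaling", {
  p <- rand_panel(15, 3, 6, seed = 13)
  p100 <- p
  p100$ratings <- p$ratings * 10
  p100$scale <- c(0, 100)
  expect_equal(intersubject_consistency(p)$consistency,
               intersubject_consistency(p100)$consistency, tolerance = 1e-12)
  expect_equal(group_consistency(p, 2)$consistency,
               group_consistency(p100, 2)$consistency, tolerance = 1e-12)
})

test_that("fisher_z is artanh with clipping at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_equal(z1, atanh(1 - 1e-7))
})

test_that("Welch comparison matches the closed-form oracle and t.test", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  got <- compare_agreement_sets(a, b)
  want <- oracle_welch_t(a, b)
  expect_equal(got$statistic, want$t)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p)
  expect_equal(got$direction, -1)

  same <- compare_agreement_sets(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("exceedance fraction uses strict inequality and excludes undefined pairs", {
  expect_equal(exceedance_fraction(c(0.5, 0.5), c(0.5, 0.5))$fraction, 0)
  expect_equal(exceedance_fraction(c(0.51, 0.51), c(0.5, 0.5))$fraction, 1)
  res <- exceedance_fraction(c(0.9, 0.8, 0.7, 0.2), c(0.5, 0.5, 0.5, 0.5))
  expect_equal(res$fraction, 0.75)
  res2 <- exceedance_fraction(c(0.9, NA), c(0.5, 0.5))
  expect_equal(res2$n_used, 1L)
  expect_equal(res2$n_excluded, 1L)
})

test_that("agreement_report ties the pieces together on a faithful annotator", {
  sim <- simulate_rating_panel(n_items = 60, n_features = 6, n_raters = 10,
                               seed = 21)
  machine <- simulate_machine_ratings(sim$truth, n_rounds = 3,
                                      round_noise_sd = 0, floor_bias = 0,
                                      fail_rate = 0, seed = 22)
  rep <- suppressWarnings(agreement_report(sim$panel, machine))
  # noiseless machine mean equals truth, so agreement beats single raters
  expect_true(all(rep$features$agreement >
                    rep$features$intersubject_consistency))
  expect_equal(glance(rep)$exceed_intersubject, 1)
  expect_s3_class(autoplot(rep), "ggplot")
})
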