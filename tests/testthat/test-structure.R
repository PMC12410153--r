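test_that("feature correlation matrix equals pairwise brute force", {
  p <- rand_panel(12, 4, 3, seed = 2, miss_rate = 0.1)
  m <- mean_over_raters(p)
  C <- feature_correlation_matrix(m)
  expect_true(isSymmetric(C))
  expect_equal(unname(diag(C)), rep(1, 4))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(C[i, j], oracle_pearson(m$values[, i], m$values[, j]))
    }
  }
})

test_that("identical and negated feature columns give +1 / -1", {
  base <- runif(10, 0, 10)
  vals <- cbind(a = base, b = base, c = 10 - base)
  rownames(vals) <- paste0("i", 1:10)
  C <- feature_correlation_matrix(vals)
  expect_equal(C["a", "b"], 1)
  expect_equal(C["a", "c"], -1)
})

test_that("zero-variance features trigger an integrity error", {
  vals <- cbind(a = runif(5), b = rep(2, 5))
  rownames(vals) <- paste0("i", 1:5)
  expect_error(feature_correlation_matrix(vals), class = "sc_integrity_error")
})

test_that("matrix similarity is the upper-triangle correlation and symmetric", {
  set.seed(4)
  A <- cor(matrix(rnorm(40), 10, 4))
  B <- cor(matrix(rnorm(40), 10, 4))
  expect_equal(matrix_similarity(A, A), 1)
  expect_equal(matrix_similarity(A, B), matrix_similarity(B, A))
  expect_equal(matrix_similarity(A, B), oracle_matrix_similarity(A, B))
})

test_that("mantel_test attains maximal statistic and minimal p when A = B", {
  set.seed(5)
  A <- cor(matrix(rnorm(60), 10, 6))
  res <- mantel_test(A, A, n_permutations = 99, seed = 1)
  expect_equal(res$statistic, 1)
  # identity is the maximum; only permutation ties can match it
  expect_lte(res$p_value, 0.5)
  expect_gte(res$p_value, 1 / 100)
})

test_that("exhaustive Mantel p equals independent enumeration for F = 4", {
  set.seed(6)
  A <- cor(matrix(rnorm(32), 8, 4))
  B <- cor(matrix(rnorm(32), 8, 4))
  got <- mantel_test(A, B, exhaustive = TRUE)
  r_obs <- oracle_matrix_similarity(A, B)
  null_r <- vapply(oracle_permutations(4), function(p) {
    oracle_matrix_similarity(A, B[p, p])
  }, numeric(1))
  expect_equal(got$statistic, r_obs)
  expect_equal(got$p_value, mean(null_r >= r_obs - 1e-12))
  expect_equal(got$n_permutations, 24L)

  # Monte-Carlo converges to the exhaustive answer
  mc <- mantel_test(A, B, n_permutations = 20000, seed = 9)
  expect_lt(abs(mc$p_value - got$p_value), 0.02)
})

test_that("mantel_test agrees with the ape implementation on a fixture", {
  skip_if_not_installed("ape")
  set.seed(7)
  A <- cor(matrix(rnorm(200), 20, 10))
  B <- cor(matrix(rnorm(200), 20, 10))
  ours <- mantel_test(A, B, n_permutations = 20000, seed = 3)
  theirs <- ape::mantel.test(A, B, nperm = 20000, alternative = "greater")
  expect_lt(abs(ours$p_value - theirs$p), 0.03)
})

test_that("pcoa reproduces classical MDS geometry", {
  set.seed(8)
  X <- matrix(rnorm(60), 12, 5)
  colnames(X) <- paste0("f", 1:5)
  C <- cor(X)

  # duplicated feature columns sit at distance zero
  X2 <- X
  X2[, 2] <- X2[, 1]
  C2 <- cor(X2)
  res2 <- pcoa(C2, k = 2)
  expect_lt(max(abs(res2$loadings[1, ] - res2$loadings[2, ])), 1e-8)

  # zero off-diagonal correlation: regular simplex, F-1 equal eigenvalues
  I5 <- diag(5)
  rownames(I5) <- colnames(I5) <- paste0("f", 1:5)
  simp <- pcoa(I5, k = 4)
  expect_equal(simp$eigenvalues, rep(simp$eigenvalues[1], 4), tolerance = 1e-10)

  # full-rank coordinates reproduce a Euclidean-embeddable distance matrix
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  Cfake <- 1 - D / max(D + 1)  # so that 1 - Cfake is Euclidean (scaled D)
  rownames(Cfake) <- colnames(Cfake) <- paste0("p", 1:6)
  resD <- pcoa(Cfake)
  Dhat <- as.matrix(dist(resD$loadings))
  expect_equal(Dhat, as.matrix(dist(pts)) / max(D + 1), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("pcoa matches cmdscale and yields centred orthogonal coordinates", {
  set.seed(9)
  C <- cor(matrix(rnorm(150), 15, 10))
  res <- pcoa(C, k = 6)
  ref <- stats::cmdscale(stats::as.dist(1 - C), k = 6, eig = TRUE)
  expect_equal(res$eigenvalues, ref$eig[1:6], tolerance = 1e-10)
  expect_equal(abs(res$loadings), abs(ref$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(res$loadings))), 1e-10)
  G <- crossprod(res$loadings)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_error(pcoa(C, k = 10), class = "sc_parameter_error")
})

test_that("loading concordance is sign- and permutation-invariant", {
  set.seed(10)
  X <- matrix(rnorm(200), 20, 10)
  colnames(X) <- paste0("f", 1:10)
  C <- cor(X)
  res <- pcoa(C, k = 5)
  conc_same <- loading_concordance(res, res)
  expect_equal(unname(diag(conc_same$abs_r)), rep(1, 5))

  flipped <- res
  flipped$loadings <- -res$loadings
  conc_flip <- loading_concordance(res, flipped)
  expect_equal(unname(diag(conc_flip$abs_r)), rep(1, 5))

  # simultaneous feature permutation of both inputs changes nothing
  perm <- sample(10)
  a2 <- res; a2$loadings <- res$loadings[perm, ]
  b2 <- flipped; b2$loadings <- flipped$loadings[perm, ]
  conc_perm <- loading_concordance(a2, b2)
  expect_equal(conc_perm$abs_r, conc_flip$abs_r, tolerance = 1e-12)

  expect_error(loading_concordance(res, res, k_max = 9),
               class = "sc_parameter_error")
  expect_s3_class(autoplot(conc_same), "ggplot")
})

test_that("concordance p-values match the t-transform of r", {
  set.seed(11)
  L1 <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("f", 1:20), NULL))
  L2 <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("f", 1:20), NULL))
  conc <- loading_concordance(L1, L2, alpha = 0.05)
  want <- cor.test(L1[, 1], L2[, 1])
  expect_equal(conc$p[1, 1], want$p.value, tolerance = 1e-12)
  expect_identical(conc$significant, conc$p < 0.05)
})
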