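#' Pearson correlation with explicit undefined flags
#'
#' Product-moment correlation on pairwise-complete observations. Rather than
#' erroring, degenerate inputs yield `NA` with a flag: fewer than `min_pairs`
#' complete pairs gives `"insufficient_pairs"`, a constant vector gives
#' `"constant_input"`. The shared primitive behind every correlation in the
#' package.
#'
#' @param x,y Numeric vectors of equal length (item-indexed).
#' @param min_pairs Minimum number of complete pairs (default 3).
#' @return A one-row tibble with columns `r`, `n`, `flag`.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))   # r = 0.8
#' @export
pearson_r <- function(x, y, min_pairs = 3L) {
  stopifnot(length(x) == length(y))
  res <- .pearson_flagged(x, y, min_pairs = min_pairs)
  tibble::tibble(r = res$r, n = res$n, flag = res$flag)
}

#' Per-feature agreement of a machine annotator with the human average
#'
#' For every feature, the Pearson correlation across items between the
#' machine's mean rating and the human pool's mean rating. Matrices are
#' aligned on shared items first (machine-failed items drop out).
#'
#' @param machine_mean,human_mean `mean_rating_matrix` objects with matching
#'   feature sets.
#' @param min_pairs Minimum complete item pairs per feature.
#' @return A tibble with columns `feature`, `agreement`, `n_items`, `flag`.
#' @export
feature_agreement <- function(machine_mean, human_mean, min_pairs = 3L) {
  al <- align_mean_matrices(machine_mean, human_mean)
  cc <- .colwise_cor(al$a$values, al$b$values, min_pairs = min_pairs)
  tibble::tibble(
    feature = colnames(al$a$values),
    agreement = cc$r,
    n_items = cc$n,
    flag = ifelse(is.na(cc$r),
                  ifelse(cc$n < min_pairs, "insufficient_pairs", "constant_input"),
                  NA_character_)
  )
}

#' Leave-one-out intersubject consistency
#'
#' For each feature: every rater's ratings are correlated with the mean of
#' all other raters over the items both sides cover, and those correlations
#' are averaged over raters. This estimates how well a single randomly drawn
#' observer tracks the population average, the single-human reliability
#' benchmark for machine agreement. Raters whose correlation is undefined
#' (constant ratings, too few items) are dropped from the mean and counted.
#'
#' @param panel A `rating_panel` with at least 2 raters.
#' @param min_pairs Minimum complete item pairs per rater-feature correlation.
#' @return A tibble with `feature`, `consistency`, `n_raters_used`,
#'   `n_raters_dropped`.
#' @export
intersubject_consistency <- function(panel, min_pairs = 3L) {
  stopifnot(inherits(panel, "rating_panel"))
  arr <- panel$ratings
  d <- dim(arr)
  if (d[3] < 2L) {
    abort("At least 2 raters are required for intersubject consistency.",
          class = "sc_insufficient_data_error")
  }
  flat <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  tot <- rowSums(flat, na.rm = TRUE)
  cnt <- rowSums(!is.na(flat))
  rsum <- matrix(0, d[2], d[3])  # feature x rater sum of r
  rn <- matrix(0L, d[2], d[3])   # defined indicator
  for (r in seq_len(d[3])) {
    xr <- flat[, r]
    n_others <- cnt - !is.na(xr)
    others_mean <- ifelse(n_others > 0,
                          (tot - ifelse(is.na(xr), 0, xr)) / n_others,
                          NA_real_)
    X <- matrix(xr, d[1], d[2])
    M <- matrix(others_mean, d[1], d[2])
    cc <- .colwise_cor(X, M, min_pairs = min_pairs)
    rsum[, r] <- ifelse(is.na(cc$r), 0, cc$r)
    rn[, r] <- !is.na(cc$r)
  }
  used <- rowSums(rn)
  tibble::tibble(
    feature = dimnames(arr)[[2]],
    consistency = ifelse(used > 0, rowSums(rsum) / used, NA_real_),
    n_raters_used = as.integer(used),
    n_raters_dropped = as.integer(d[3] - used)
  )
}

#' Enumerate unordered disjoint rater splits
#'
#' All unordered pairs of disjoint rater subsets of size `group_size` drawn
#' from `n_raters` raters: C(R, g) * C(R - g, g) / 2 pairs (each unordered
#' pair of same-size groups would otherwise be enumerated twice). For R = 10,
#' g = 5 this is the 126 half-splits of the pool.
#'
#' @param n_raters Total number of raters R.
#' @param group_size Size g of each group; requires R >= 2 g.
#' @return A list of two-element lists of integer index vectors.
#' @export
rater_splits <- function(n_raters, group_size) {
  if (n_raters < 2L * group_size) {
    abort("Need at least 2 * group_size raters to split.",
          class = "sc_parameter_error")
  }
  first <- combn(n_raters, group_size, simplify = FALSE)
  out <- vector("list", 0L)
  for (a in first) {
    rest <- setdiff(seq_len(n_raters), a)
    second <- combn(rest, group_size, simplify = FALSE)
    for (b in second) {
      if (min(a) < min(b)) out[[length(out) + 1L]] <- list(a = a, b = b)
    }
  }
  out
}

#' Split-group consistency of a rater pool
#'
#' The pool is split into two disjoint groups of `group_size` raters in every
#' possible way; for each split the two group-mean rating vectors are
#' correlated per feature, and the correlations are averaged over splits.
#' With 10 raters and groups of 5 this evaluates all 126 half-splits; it is
#' the group-of-humans reliability benchmark.
#'
#' @param panel A `rating_panel`.
#' @param group_size Raters per group (default 5).
#' @param min_pairs Minimum complete item pairs per split correlation.
#' @return A tibble with `feature`, `consistency`, `n_splits_used`.
#' @export
group_consistency <- function(panel, group_size = 5L, min_pairs = 3L) {
  stopifnot(inherits(panel, "rating_panel"))
  arr <- panel$ratings
  d <- dim(arr)
  splits <- rater_splits(d[3], group_size)
  flat <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  rsum <- numeric(d[2])
  rn <- integer(d[2])
  for (sp in splits) {
    ma <- .subset_mean(flat, sp$a, d)
    mb <- .subset_mean(flat, sp$b, d)
    cc <- .colwise_cor(ma, mb, min_pairs = min_pairs)
    rsum <- rsum + ifelse(is.na(cc$r), 0, cc$r)
    rn <- rn + !is.na(cc$r)
  }
  tibble::tibble(
    feature = dimnames(arr)[[2]],
    consistency = ifelse(rn > 0, rsum / rn, NA_real_),
    n_splits_used = as.integer(rn)
  )
}

.subset_mean <- function(flat, idx, d) {
  sub <- flat[, idx, drop = FALSE]
  n <- rowSums(!is.na(sub))
  m <- ifelse(n > 0, rowSums(sub, na.rm = TRUE) / n, NA_real_)
  matrix(m, d[1], d[2])
}

#' Fisher z-transformation
#'
#' Variance-stabilising `artanh` transform of a correlation. Values at or
#' beyond +/- 1 are clipped to +/- (1 - 1e-7) with a warning so downstream
#' t-tests stay finite.
#'
#' @param r Numeric vector of correlations.
#' @return `atanh(r)` after clipping.
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-7
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warn("Correlations with |r| >= 1 clipped to +/-(1 - 1e-7) before atanh.")
    r <- .clip(r, -lim, lim)
  }
  atanh(r)
}

#' Compare two sets of Fisher-z agreement values
#'
#' Welch (unequal-variance) two-sample t-test across features between two
#' vectors of Fisher-z transformed correlations, e.g. machine agreement vs
#' intersubject consistency. Two-sided p; `direction` is the sign of
#' mean(z_a) - mean(z_b).
#'
#' @param z_a,z_b Numeric vectors of Fisher-z values (NAs dropped).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `direction`,
#'   `mean_diff`, `n_a`, `n_b`.
#' @export
compare_agreement_sets <- function(z_a, z_b) {
  z_a <- z_a[!is.na(z_a)]
  z_b <- z_b[!is.na(z_b)]
  if (length(z_a) < 2L || length(z_b) < 2L) {
    abort("Each set needs at least 2 defined z values.",
          class = "sc_insufficient_data_error")
  }
  md <- mean(z_a) - mean(z_b)
  if (sd(z_a) == 0 && sd(z_b) == 0) {
    return(tibble::tibble(statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, direction = sign(md),
                          mean_diff = md,
                          n_a = length(z_a), n_b = length(z_b)))
  }
  tt <- stats::t.test(z_a, z_b, var.equal = FALSE)
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    direction = sign(md),
    mean_diff = md,
    n_a = length(z_a),
    n_b = length(z_b)
  )
}

#' Fraction of features where agreement exceeds a benchmark
#'
#' Strict inequality ("higher than"); feature pairs where either value is
#' undefined are excluded and counted.
#'
#' @param agreement,benchmark Numeric vectors aligned on the feature axis.
#' @return A one-row tibble: `fraction`, `n_exceed`, `n_used`, `n_excluded`.
#' @export
exceedance_fraction <- function(agreement, benchmark) {
  stopifnot(length(agreement) == length(benchmark))
  ok <- !is.na(agreement) & !is.na(benchmark)
  n_exceed <- sum(agreement[ok] > benchmark[ok])
  tibble::tibble(
    fraction = if (sum(ok)) n_exceed / sum(ok) else NA_real_,
    n_exceed = n_exceed,
    n_used = sum(ok),
    n_excluded = sum(!ok)
  )
}
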