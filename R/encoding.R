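#' Stimulus presentation schedule
#'
#' Holds clip onsets/durations plus the acquisition timing (TR, number of
#' volumes) of an event-related run. Onsets must be ascending and
#' non-overlapping, and the last clip must end within the acquisition.
#'
#' @param clips Data frame with columns `item_id`, `onset` (s), `duration`
#'   (s).
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of acquired volumes.
#' @return A `stimulus_schedule`.
#' @export
stimulus_schedule <- function(clips, tr, n_volumes) {
  clips <- tibble::as_tibble(clips)
  need <- c("item_id", "onset", "duration")
  if (!all(need %in% names(clips))) {
    abort("`clips` needs columns item_id, onset, duration.",
          class = "sc_schema_error")
  }
  stopifnot(tr > 0, n_volumes >= 1L)
  o <- clips$onset; d <- clips$duration
  if (is.unsorted(o, strictly = TRUE) && nrow(clips) > 1L) {
    abort("Clip onsets must be strictly ascending.", class = "sc_timing_error")
  }
  if (nrow(clips) > 1L && any(o[-1] < (o + d)[-nrow(clips)] - 1e-9)) {
    abort("Clips overlap in time.", class = "sc_timing_error")
  }
  if (nrow(clips) && max(o + d) > tr * n_volumes + 1e-9) {
    abort("Schedule overruns the acquisition window.",
          class = "sc_timing_error")
  }
  structure(list(clips = clips, tr = tr, n_volumes = as.integer(n_volumes)),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> %d clips, TR %.3g s, %d volumes (%.1f s)\n",
              nrow(x$clips), x$tr, x$n_volumes, x$tr * x$n_volumes))
  invisible(x)
}

#' Read/write a stimulus schedule as CSV
#'
#' CSV columns: `item_id`, `onset_s`, `duration_s`; TR and volume count are
#' passed separately.
#'
#' @param path CSV path.
#' @param tr,n_volumes Acquisition timing.
#' @return A `stimulus_schedule`.
#' @export
read_schedule_csv <- function(path, tr, n_volumes) {
  df <- readr::read_csv(path, col_types = readr::cols(
    item_id = readr::col_character(),
    onset_s = readr::col_double(),
    duration_s = readr::col_double()
  ), progress = FALSE)
  stimulus_schedule(
    tibble::tibble(item_id = df$item_id, onset = df$onset_s,
                   duration = df$duration_s),
    tr = tr, n_volumes = n_volumes
  )
}

#' @rdname read_schedule_csv
#' @param schedule A `stimulus_schedule` to write.
#' @export
write_schedule_csv <- function(schedule, path) {
  readr::write_csv(
    tibble::tibble(item_id = schedule$clips$item_id,
                   onset_s = schedule$clips$onset,
                   duration_s = schedule$clips$duration),
    path, progress = FALSE
  )
  invisible(path)
}

#' Canonical double-gamma haemodynamic response function
#'
#' The conventional canonical HRF: a gamma-density response (shape 6,
#' scale 1, peaking near 5 s) minus a gamma-density undershoot (shape 16,
#' scale 1) scaled by 1/6, sampled on a grid of width `dt` over 32 s of
#' support and normalised to unit peak.
#'
#' @param dt Sampling interval in seconds, `0 < dt <= 1`.
#' @return Numeric kernel sampled at `t = 0, dt, 2 dt, ..., 32`.
#' @examples
#' h <- canonical_hrf(0.1)
#' (which.max(h) - 1) * 0.1   # peak near 5 s
#' @export
canonical_hrf <- function(dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0 || dt > 1) {
    abort("`dt` must be a single value in (0, 1].", class = "sc_parameter_error")
  }
  t <- seq(0, 32, by = dt)
  h <- dgamma(t, shape = 6, scale = 1) - dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' Build an HRF-convolved feature regressor
#'
#' A boxcar at microtime resolution (`tr / microtime`) carries each clip's
#' feature intensity over the clip's duration; the boxcar is convolved with
#' the canonical double-gamma HRF, sampled at the volume acquisition times
#' (the start of each TR), and mean-centred.
#'
#' @param schedule A [stimulus_schedule()].
#' @param feature_values Named numeric vector of the feature's intensity per
#'   clip (`names` = `item_id`); every scheduled clip must be covered.
#' @param microtime Microtime bins per TR (default 16).
#' @return Numeric vector of length `n_volumes` (mean-centred).
#' @export
build_feature_regressor <- function(schedule, feature_values, microtime = 16L) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  ids <- schedule$clips$item_id
  miss <- setdiff(ids, names(feature_values))
  if (length(miss)) {
    abort(paste0("Feature values missing for scheduled clip(s): ",
                 paste(head(miss, 5), collapse = ", ")),
          class = "sc_coverage_error")
  }
  if (anyNA(feature_values[ids])) {
    abort("Feature values for scheduled clips contain NA.",
          class = "sc_coverage_error")
  }
  dt <- schedule$tr / microtime
  n_grid <- schedule$n_volumes * microtime
  box <- numeric(n_grid)
  for (i in seq_along(ids)) {
    from <- floor(schedule$clips$onset[i] / dt) + 1L
    to <- min(ceiling((schedule$clips$onset[i] + schedule$clips$duration[i]) / dt),
              n_grid)
    box[from:to] <- feature_values[[ids[i]]]
  }
  kern <- canonical_hrf(dt)
  conv <- .convolve_causal(box, kern)
  vol_idx <- (seq_len(schedule$n_volumes) - 1L) * microtime + 1L
  reg <- conv[vol_idx]
  reg - mean(reg)
}

# causal discrete convolution truncated to the length of x
.convolve_causal <- function(x, k) {
  n <- length(x)
  full <- stats::convolve(x, rev(k), type = "open")
  full[seq_len(n)]
}

#' Build the full design matrix of feature regressors
#'
#' One HRF-convolved, mean-centred regressor per feature.
#'
#' @param schedule A [stimulus_schedule()].
#' @param feature_table Item x feature matrix (or `mean_rating_matrix`) of
#'   intensities; rownames are item ids covering every scheduled clip.
#' @param microtime Microtime bins per TR.
#' @return `n_volumes` x F matrix with feature colnames.
#' @export
build_design <- function(schedule, feature_table, microtime = 16L) {
  vals <- if (inherits(feature_table, "mean_rating_matrix")) {
    feature_table$values
  } else {
    as.matrix(feature_table)
  }
  out <- vapply(
    colnames(vals),
    function(f) build_feature_regressor(schedule,
                                        setNames(vals[, f], rownames(vals)),
                                        microtime = microtime),
    numeric(schedule$n_volumes)
  )
  colnames(out) <- colnames(vals)
  out
}

#' Massive-univariate first-level betas
#'
#' Ordinary least squares of every voxel's time series on `[intercept,
#' regressor]`, fitted independently per voxel (simple regression: each
#' feature regressor is fitted separately, never jointly).
#'
#' @param bold Voxel x time numeric matrix.
#' @param regressor Numeric regressor of length `ncol(bold)`; must be
#'   non-constant.
#' @return Numeric vector: the regressor coefficient per voxel.
#' @export
first_level_betas <- function(bold, regressor) {
  bold <- as.matrix(bold)
  if (ncol(bold) != length(regressor)) {
    abort("Time axes of `bold` and `regressor` differ.",
          class = "sc_alignment_error")
  }
  xc <- regressor - mean(regressor)
  sxx <- sum(xc^2)
  if (sxx == 0) {
    abort("Constant regressor.", class = "sc_parameter_error")
  }
  as.numeric(bold %*% xc) / sxx
}

#' Group-level one-sample t-map
#'
#' Per-voxel one-sample t-test of subject betas against zero
#' (`t = mean / (sd / sqrt(n))`, df = n - 1) with one-sided p-values for a
#' positive effect. Voxels with zero between-subject variance get `NA` p and
#' are counted in the `n_flagged` attribute.
#'
#' @param betas Subject x voxel matrix (>= 2 subjects).
#' @return A list with `t`, `p` (one-sided positive), `n_subjects`,
#'   `n_flagged`.
#' @export
group_one_sample_t <- function(betas) {
  betas <- as.matrix(betas)
  n <- nrow(betas)
  if (n < 2L) {
    abort("At least 2 subjects are required.", class = "sc_parameter_error")
  }
  m <- colMeans(betas)
  s2 <- (colSums(betas^2) - n * m^2) / (n - 1)
  s <- sqrt(pmax(s2, 0))
  zero <- s == 0
  tmap <- ifelse(zero, NA_real_, m / (s / sqrt(n)))
  pmap <- pt(tmap, df = n - 1, lower.tail = FALSE)
  list(t = tmap, p = pmap, n_subjects = n, n_flagged = sum(zero))
}

#' Threshold a p-map
#'
#' Uncorrected (`p < alpha`) or Bonferroni voxel-level family-wise-error
#' (`p < alpha / V` over the V in-mask voxels) thresholding. Bonferroni is a
#' conservative stand-in for voxel-level FWE control.
#'
#' @param p Numeric p-value map.
#' @param alpha Significance level in (0, 1).
#' @param correction `"none"` or `"bonferroni_fwe"`.
#' @param mask Logical analysis mask (default: all voxels with defined p).
#' @return Logical binary map (TRUE = passing, only inside the mask).
#' @export
threshold_map <- function(p, alpha, correction = c("none", "bonferroni_fwe"),
                          mask = NULL) {
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "sc_parameter_error")
  }
  mask <- mask %||% !is.na(p)
  if (!any(mask)) abort("Empty analysis mask.", class = "sc_parameter_error")
  cutoff <- if (correction == "bonferroni_fwe") alpha / sum(mask) else alpha
  out <- !is.na(p) & p < cutoff & mask
  out
}

#' Positive and negative predictive values of a binary map
#'
#' Confusion of a test map against a reference map over in-mask voxels:
#' `PPV = TP / (TP + FP)`, `NPV = TN / (TN + FN)`. An empty positive (or
#' negative) test set leaves the corresponding value `NA` with a flag.
#'
#' @param test,reference Logical binary maps on the same mask.
#' @param mask Logical analysis mask (default: all voxels).
#' @return One-row tibble: `ppv`, `npv`, `tp`, `fp`, `tn`, `fn`, `flag`.
#' @export
ppv_npv <- function(test, reference, mask = NULL) {
  if (length(test) != length(reference)) {
    abort("`test` and `reference` maps differ in length.",
          class = "sc_alignment_error")
  }
  mask <- mask %||% rep(TRUE, length(test))
  t_ <- test[mask]; r_ <- reference[mask]
  tp <- sum(t_ & r_); fp <- sum(t_ & !r_)
  tn <- sum(!t_ & !r_); fn <- sum(!t_ & r_)
  flag <- c(if (tp + fp == 0L) "no_test_positives",
            if (tn + fn == 0L) "no_test_negatives")
  tibble::tibble(
    ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0L) tn / (tn + fn) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn,
    flag = if (length(flag)) paste(flag, collapse = ";") else NA_character_
  )
}

#' Cumulative social-tuning map
#'
#' Per-voxel count of features whose binary (thresholded, positive-effect)
#' map passes at that voxel: a map of how broadly each voxel is tuned to the
#' rated features.
#'
#' @param binary_maps Voxel x feature logical matrix (or list of logical
#'   vectors).
#' @return Integer count map in `[0, F]`.
#' @export
cumulative_map <- function(binary_maps) {
  if (is.list(binary_maps)) binary_maps <- do.call(cbind, binary_maps)
  as.integer(rowSums(binary_maps))
}

#' Spatial correlation of two maps
#'
#' Pearson correlation of two real-valued maps over in-mask voxels; `NA`
#' with a flag if either map is constant there.
#'
#' @param map_a,map_b Numeric maps of equal length.
#' @param mask Logical analysis mask.
#' @return One-row tibble `r`, `n`, `flag` (as [pearson_r()]).
#' @export
spatial_correlation <- function(map_a, map_b, mask = NULL) {
  if (length(map_a) != length(map_b)) {
    abort("Maps differ in length.", class = "sc_alignment_error")
  }
  mask <- mask %||% rep(TRUE, length(map_a))
  pearson_r(map_a[mask], map_b[mask])
}
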