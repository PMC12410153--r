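#' Simulate a human rater pool with planted latent structure
#'
#' Generates a rating panel whose true per-item feature intensities arise
#' from a low-dimensional latent model: item scores (items x K, standard
#' normal) times feature loadings (features x K, with geometrically decaying
#' component scales so the planted dimensions are well separated), affinely
#' mapped onto the 0-10 analysis scale and clipped. Each rater observes the
#' truth plus independent Gaussian noise, clipped to the scale; the noise sd
#' of each feature is calibrated so a single rater's expected leave-one-out
#' consistency matches `consistency_profile` (see Details).
#'
#' @details With signal variance s^2 and noise variance v s^2, the expected
#' correlation between one rater and the mean of the other R - 1 raters is
#' `1 / sqrt((1 + v) (1 + v / (R - 1)))`; the generator inverts this map for
#' the requested consistency. Defaults mirror a typical social-perception
#' rating study: 234 items, 136 features, 10 raters per item, an
#' 8-dimensional latent structure, and a 0-10 scale.
#'
#' @param n_items,n_features,n_raters Panel dimensions.
#' @param k_latent Planted latent dimensionality (default 8).
#' @param consistency_profile Target expected single-rater consistency,
#'   scalar or per-feature vector with values in (0, 1).
#' @param seed Integer seed; required for reproducibility.
#' @param intensity_center,intensity_sd Centre and spread of the true
#'   intensities on the 0-10 scale before clipping.
#' @param modality Modality label passed to the panel.
#' @return A list with `panel` (a [rating_panel()]) and `truth` (a
#'   `rating_ground_truth` list: `latent_loadings`, `item_scores`,
#'   `true_intensity`, `rater_noise_sd`, `consistency_profile`).
#' @export
simulate_rating_panel <- function(n_items = 234L, n_features = 136L,
                                  n_raters = 10L, k_latent = 8L,
                                  consistency_profile = 0.6, seed,
                                  intensity_center = 4,
                                  intensity_sd = 1.8,
                                  modality = "video") {
  if (missing(seed)) abort("`seed` is required.", class = "sc_parameter_error")
  stopifnot(n_items >= 1L, n_features >= 1L, n_raters >= 1L, k_latent >= 1L)
  prof <- rep_len(consistency_profile, n_features)
  if (any(prof <= 0 | prof >= 1)) {
    abort("`consistency_profile` values must lie strictly in (0, 1).",
          class = "sc_parameter_error")
  }
  set.seed(seed)
  items <- sprintf("item%03d", seq_len(n_items))
  feats <- sprintf("feat%03d", seq_len(n_features))
  raters <- sprintf("rater%02d", seq_len(n_raters))

  truth <- .make_rating_truth(n_items, n_features, k_latent,
                              intensity_center, intensity_sd, items, feats)
  noise_sd <- .calibrate_rater_noise(truth$true_intensity, prof, n_raters)

  arr <- array(NA_real_, dim = c(n_items, n_features, n_raters),
               dimnames = list(items, feats, raters))
  for (r in seq_len(n_raters)) {
    noise <- matrix(rnorm(n_items * n_features), n_items, n_features)
    noise <- sweep(noise, 2L, noise_sd, `*`)
    arr[, , r] <- .clip(truth$true_intensity + noise, 0, 10)
  }
  truth$rater_noise_sd <- noise_sd
  truth$consistency_profile <- prof
  list(panel = rating_panel(arr, scale = c(0, 10), modality = modality),
       truth = truth)
}

.make_rating_truth <- function(n_items, n_features, k_latent,
                               center, spread, items, feats) {
  # geometric decay keeps adjacent planted eigenvalues well separated so the
  # latent dimensions are mutually identifiable from finite noisy samples
  comp_scale <- 0.75^(seq_len(k_latent) - 1)
  loadings <- matrix(rnorm(n_features * k_latent), n_features, k_latent)
  loadings <- sweep(loadings, 2L, comp_scale, `*`)
  scores <- matrix(rnorm(n_items * k_latent), n_items, k_latent)
  raw <- scores %*% t(loadings)
  raw <- raw / sd(as.vector(raw))
  ti <- .clip(center + spread * raw, 0, 10)
  dimnames(ti) <- list(items, feats)
  rownames(loadings) <- feats
  colnames(loadings) <- paste0("dim", seq_len(k_latent))
  rownames(scores) <- items
  colnames(scores) <- colnames(loadings)
  structure(list(latent_loadings = loadings, item_scores = scores,
                 true_intensity = ti),
            class = "rating_ground_truth")
}

# Invert c = 1 / sqrt((1 + v)(1 + v/m)), m = R - 1, for the noise-to-signal
# variance ratio v, then scale by each feature's realised signal sd.
.calibrate_rater_noise <- function(true_intensity, profile, n_raters) {
  m <- max(n_raters - 1L, 1L)
  inv <- 1 / profile^2
  v <- m / 2 * (-(1 + 1 / m) + sqrt((1 + 1 / m)^2 + 4 * (inv - 1) / m))
  sig_sd <- apply(true_intensity, 2L, sd)
  sig_sd[sig_sd == 0] <- 1e-6
  sig_sd * sqrt(pmax(v, 0))
}

#' Draw an independent rater pool from an existing ground truth
#'
#' Generates a new panel of raters observing the same true intensities with
#' the same calibrated per-feature noise, e.g. to obtain two independent
#' noisy replicates of one planted structure.
#'
#' @param truth A `rating_ground_truth` from [simulate_rating_panel()]
#'   (must carry `rater_noise_sd`).
#' @param n_raters Number of raters in the new pool.
#' @param seed Integer seed.
#' @param modality Modality label.
#' @return A [rating_panel()].
#' @export
resample_rating_panel <- function(truth, n_raters = 10L, seed,
                                  modality = "video") {
  if (missing(seed)) abort("`seed` is required.", class = "sc_parameter_error")
  stopifnot(inherits(truth, "rating_ground_truth"))
  if (is.null(truth$rater_noise_sd)) {
    abort("`truth` lacks calibrated rater noise; generate it with simulate_rating_panel().",
          class = "sc_parameter_error")
  }
  set.seed(seed)
  ti <- truth$true_intensity
  raters <- sprintf("rater%02d", seq_len(n_raters))
  arr <- array(NA_real_, dim = c(nrow(ti), ncol(ti), n_raters),
               dimnames = c(dimnames(ti), list(raters)))
  for (r in seq_len(n_raters)) {
    noise <- matrix(rnorm(length(ti)), nrow(ti), ncol(ti))
    noise <- sweep(noise, 2L, truth$rater_noise_sd, `*`)
    arr[, , r] <- .clip(ti + noise, 0, 10)
  }
  rating_panel(arr, scale = c(0, 10), modality = modality)
}

#' Simulate a multi-round machine annotator
#'
#' Each collection round observes the ground-truth intensities through a
#' "floor bias" (values below the scale midpoint 5 are multiplied by
#' `1 - floor_bias`, values at or above 5 pass unchanged, matching the
#' empirical observation that machine annotators under-rate weakly present
#' features) plus Gaussian round noise, clipped to 0-10. A `fail_rate`
#' fraction of items is refused in every round (content-moderation style
#' failures) and is missing throughout.
#'
#' @param truth A `rating_ground_truth` from [simulate_rating_panel()].
#' @param n_rounds Number of collection rounds (default 5).
#' @param round_noise_sd Gaussian sd of per-round noise.
#' @param floor_bias Relative shrinkage of sub-midpoint values, in `[0, 1)`.
#' @param fail_rate Probability an item fails in all rounds, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [machine_rating_set()].
#' @export
simulate_machine_ratings <- function(truth, n_rounds = 5L,
                                     round_noise_sd = 0.5,
                                     floor_bias = 0, fail_rate = 0, seed) {
  if (missing(seed)) abort("`seed` is required.", class = "sc_parameter_error")
  stopifnot(inherits(truth, "rating_ground_truth"), n_rounds >= 1L)
  if (floor_bias < 0 || floor_bias >= 1) {
    abort("`floor_bias` must lie in [0, 1).", class = "sc_parameter_error")
  }
  if (fail_rate < 0 || fail_rate >= 1) {
    abort("`fail_rate` must lie in [0, 1).", class = "sc_parameter_error")
  }
  set.seed(seed)
  ti <- truth$true_intensity
  biased <- ifelse(ti < 5, ti * (1 - floor_bias), ti)
  n_items <- nrow(ti); n_features <- ncol(ti)
  rounds <- sprintf("round%d", seq_len(n_rounds))
  arr <- array(NA_real_, dim = c(n_items, n_features, n_rounds),
               dimnames = c(dimnames(ti), list(rounds)))
  for (k in seq_len(n_rounds)) {
    noise <- matrix(rnorm(n_items * n_features, sd = round_noise_sd),
                    n_items, n_features)
    arr[, , k] <- .clip(biased + noise, 0, 10)
  }
  failed <- runif(n_items) < fail_rate
  arr[failed, , ] <- NA_real_
  machine_rating_set(arr, scale = c(0, 10))
}

#' Apply the machine floor bias to a vector of intensities
#'
#' Exposed for inspection/testing of the bias model: values below 5 are
#' multiplied by `1 - floor_bias`, values at or above 5 are unchanged
#' (continuous at 5 when `floor_bias = 0`).
#'
#' @param x Numeric intensities on the 0-10 scale.
#' @param floor_bias Shrinkage in `[0, 1)`.
#' @return The biased intensities.
#' @export
floor_biased <- function(x, floor_bias) {
  if (floor_bias < 0 || floor_bias >= 1) {
    abort("`floor_bias` must lie in [0, 1).", class = "sc_parameter_error")
  }
  ifelse(x < 5, x * (1 - floor_bias), x)
}
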