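#' Simulate an event-related stimulus schedule
#'
#' Places `n_clips` clips back-to-back (with a short inter-stimulus interval)
#' inside an acquisition of `n_volumes` volumes at repetition time `tr`,
#' mirroring a continuous socioemotional movie-medley design. Durations are
#' drawn uniformly from `duration_range`. If the drawn clips do not fit in
#' the acquisition window the call fails with a timing error rather than
#' silently truncating.
#'
#' @param n_clips Number of clips (default 96).
#' @param tr Repetition time in seconds (default 2.6).
#' @param n_volumes Number of volumes (default 467).
#' @param duration_range Min/max clip duration in seconds.
#' @param isi Inter-stimulus interval in seconds.
#' @param item_ids Optional clip identifiers (default `item001`, ...).
#' @param seed Integer seed.
#' @return A [stimulus_schedule()].
#' @export
simulate_schedule <- function(n_clips = 96L, tr = 2.6, n_volumes = 467L,
                              duration_range = c(5, 15), isi = 0.6,
                              item_ids = NULL, seed) {
  if (missing(seed)) abort("`seed` is required.", class = "sc_parameter_error")
  set.seed(seed)
  durs <- runif(n_clips, duration_range[1], duration_range[2])
  onsets <- cumsum(c(isi, head(durs, -1) + isi))
  ids <- item_ids %||% sprintf("item%03d", seq_len(n_clips))
  stopifnot(length(ids) == n_clips)
  stimulus_schedule(
    tibble::tibble(item_id = ids, onset = onsets, duration = durs),
    tr = tr, n_volumes = n_volumes
  )
}

#' Simulate event-related BOLD data with known voxel tuning
#'
#' Generates per-subject voxel x time BOLD matrices from a linear encoding
#' model: a sparse voxel x feature matrix of positive true betas defines
#' which voxels are tuned to which features; each subject's betas are the
#' truth plus Gaussian jitter on the tuned cells (untuned voxel-feature
#' pairs carry no subject-specific response, keeping tuning sparse),
#' multiplied into the HRF-convolved feature design and summed, plus white
#' Gaussian noise.
#'
#' @param schedule A [stimulus_schedule()].
#' @param feature_values Item x feature matrix (or `mean_rating_matrix`) of
#'   stimulus intensities covering all scheduled clips.
#' @param n_subjects,n_voxels Simulated sample dimensions.
#' @param tuned_fraction Probability that a voxel-feature cell is tuned
#'   (sparse; default 0.05, at most ~10 percent is realistic).
#' @param beta_scale True beta at tuned cells.
#' @param noise_sd Temporal white-noise sd.
#' @param beta_jitter_sd Between-subject sd of the betas.
#' @param microtime Microtime bins per TR for the design.
#' @param seed Integer seed.
#' @return A list with `bold` (list of `n_subjects` voxel x time matrices),
#'   `design` (n_volumes x F), and `truth` (a `bold_ground_truth` list:
#'   `true_beta`, `tuned_mask`, `noise_sd`, `beta_jitter_sd`).
#' @export
simulate_bold <- function(schedule, feature_values, n_subjects = 20L,
                          n_voxels = 2000L, tuned_fraction = 0.05,
                          beta_scale = 1, noise_sd = 1,
                          beta_jitter_sd = 0, microtime = 16L, seed) {
  if (missing(seed)) abort("`seed` is required.", class = "sc_parameter_error")
  stopifnot(n_subjects >= 1L, n_voxels >= 1L,
            tuned_fraction >= 0, tuned_fraction <= 1,
            noise_sd >= 0, beta_jitter_sd >= 0)
  design <- build_design(schedule, feature_values, microtime = microtime)
  n_features <- ncol(design)
  set.seed(seed)
  tuned <- matrix(runif(n_voxels * n_features) < tuned_fraction,
                  n_voxels, n_features)
  true_beta <- tuned * beta_scale
  colnames(true_beta) <- colnames(tuned) <- colnames(design)
  bold <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subj_beta <- true_beta +
      tuned * matrix(rnorm(n_voxels * n_features, sd = beta_jitter_sd),
                     n_voxels, n_features)
    signal <- subj_beta %*% t(design)
    noise <- matrix(rnorm(n_voxels * schedule$n_volumes, sd = noise_sd),
                    n_voxels, schedule$n_volumes)
    bold[[s]] <- signal + noise
  }
  names(bold) <- sprintf("sub%02d", seq_len(n_subjects))
  truth <- structure(
    list(true_beta = true_beta, tuned_mask = tuned,
         noise_sd = noise_sd, beta_jitter_sd = beta_jitter_sd),
    class = "bold_ground_truth"
  )
  list(bold = bold, design = design, truth = truth)
}

#' Choose the temporal noise sd for a target group-level effect size
#'
#' For planning simulations: with true beta `beta_scale`, between-subject
#' jitter `beta_jitter_sd`, and a given design, the across-subject sd of the
#' estimated beta at a tuned voxel is
#' `sqrt(beta_jitter_sd^2 + noise_sd^2 / sum(xc^2))` per feature regressor
#' (xc the centred regressor). This helper returns the `noise_sd` that makes
#' the group-level Cohen's d equal `target_d` (averaged over features).
#'
#' Jitter on feature g of the same voxel leaks into feature f's
#' simple-regression beta with coefficient `(x_g . x_f) / |x_f|^2` when the
#' regressors are correlated; since jitter lives only on tuned cells, the
#' expected leakage multiplier at a voxel tuned to f is
#' `L_f = 1 + tuned_fraction * sum_{g != f} a_gf^2`, which is accounted for
#' here so the realised d matches the target.
#'
#' @param design n_volumes x F design matrix of centred regressors.
#' @param target_d Desired effect size d = beta / sd(beta-hat).
#' @param beta_scale True beta at tuned voxels.
#' @param beta_jitter_sd Between-subject beta sd (tuned cells).
#' @param tuned_fraction Sparsity of tuning used for the leakage expectation.
#' @return The required `noise_sd` (scalar).
#' @export
calibrate_bold_noise <- function(design, target_d, beta_scale = 1,
                                 beta_jitter_sd = 0, tuned_fraction = 0.05) {
  Xc <- sweep(as.matrix(design), 2L, colMeans(design))
  sxx <- colSums(Xc^2)
  G <- crossprod(Xc)                       # x_g . x_f
  A <- sweep(G, 2L, sxx, `/`)              # leakage coefficients a[g, f]
  L <- 1 + tuned_fraction * (colSums(A^2) - 1)
  need_var <- (beta_scale / target_d)^2 - beta_jitter_sd^2 * L
  if (any(need_var <= 0)) {
    abort("`beta_jitter_sd` alone already exceeds the target effect size for some regressor.",
          class = "sc_parameter_error")
  }
  sqrt(mean(need_var * sxx))
}
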