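#' Fit the massive-univariate encoding model for all features
#'
#' For each feature regressor and each subject, fits the per-voxel simple
#' regression ([first_level_betas()]); subject beta maps then enter a group
#' one-sample t-test per feature with one-sided (positive) p-values.
#'
#' @param bold List of subject voxel x time matrices (equal dimensions).
#' @param design n_volumes x F matrix of feature regressors (see
#'   [build_design()]).
#' @param mask Optional logical voxel mask; defaults to all voxels.
#' @return An `encoding_fit`: list with `betas` (subject x voxel x feature
#'   array), `group_beta` (voxel x feature mean betas), `t`, `p` (voxel x
#'   feature), `mask`, `n_subjects`.
#' @export
fit_encoding <- function(bold, design, mask = NULL) {
  stopifnot(is.list(bold), length(bold) >= 1L)
  design <- as.matrix(design)
  n_sub <- length(bold)
  n_vox <- nrow(bold[[1]])
  n_feat <- ncol(design)
  mask <- mask %||% rep(TRUE, n_vox)
  betas <- array(NA_real_, dim = c(n_sub, n_vox, n_feat),
                 dimnames = list(names(bold), NULL, colnames(design)))
  Xc <- sweep(design, 2L, colMeans(design))
  sxx <- colSums(Xc^2)
  if (any(sxx == 0)) {
    abort("Constant regressor in the design.", class = "sc_parameter_error")
  }
  for (s in seq_len(n_sub)) {
    B <- as.matrix(bold[[s]])
    if (!all(dim(B) == c(n_vox, nrow(design)))) {
      abort("All subjects must share voxel and time dimensions matching the design.",
            class = "sc_alignment_error")
    }
    betas[s, , ] <- sweep(B %*% Xc, 2L, sxx, `/`)
  }
  tmap <- matrix(NA_real_, n_vox, n_feat, dimnames = list(NULL, colnames(design)))
  pmap <- tmap
  for (f in seq_len(n_feat)) {
    gt <- group_one_sample_t(betas[, , f, drop = TRUE])
    tmap[, f] <- gt$t
    pmap[, f] <- gt$p
  }
  structure(
    list(betas = betas,
         group_beta = apply(betas, c(2L, 3L), mean),
         t = tmap, p = pmap, mask = mask, n_subjects = n_sub),
    class = "encoding_fit"
  )
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("<encoding_fit> %d subjects, %d voxels, %d features\n",
              x$n_subjects, nrow(x$t), ncol(x$t)))
  invisible(x)
}

#' @rdname tidy.rating_panel
#' @param alpha Uncorrected threshold used to count suprathreshold voxels.
#' @export
tidy.encoding_fit <- function(x, alpha = 0.001, ...) {
  tibble::tibble(
    feature = colnames(x$t),
    n_voxels_positive = vapply(seq_len(ncol(x$p)), function(f) {
      sum(threshold_map(x$p[, f], alpha, "none", x$mask))
    }, integer(1)),
    max_t = apply(x$t, 2L, max, na.rm = TRUE)
  )
}

#' Compare machine- and human-derived encoding results
#'
#' Stage-3 comparison of two [fit_encoding()] results over the same voxels:
#' per-feature spatial correlation of unthresholded group beta maps;
#' per-feature PPV/NPV of the test (machine) maps against the reference
#' (human) maps at a lenient uncorrected threshold and a conservative
#' Bonferroni FWE threshold; and the spatial correlation of the two
#' cumulative maps (per-voxel counts of features passing the lenient
#' threshold).
#'
#' @param fit_test Encoding fit from the machine stimulus model.
#' @param fit_reference Encoding fit from the human stimulus model (treated
#'   as ground truth for predictive values).
#' @param alpha_lenient Uncorrected threshold (default 0.001).
#' @param alpha_fwe Voxel-level FWE (Bonferroni) threshold (default 0.05).
#' @return An `encoding_comparison`: list with `features` (per-feature
#'   tibble), `cumulative` (list: `test`, `reference` count maps and
#'   `spatial_r`), and the thresholds.
#' @export
compare_encodings <- function(fit_test, fit_reference,
                              alpha_lenient = 0.001, alpha_fwe = 0.05) {
  stopifnot(inherits(fit_test, "encoding_fit"),
            inherits(fit_reference, "encoding_fit"))
  if (!identical(colnames(fit_test$t), colnames(fit_reference$t)) ||
      nrow(fit_test$t) != nrow(fit_reference$t)) {
    abort("Encoding fits must share voxels and feature set.",
          class = "sc_alignment_error")
  }
  mask <- fit_test$mask & fit_reference$mask
  feats <- colnames(fit_test$t)
  rows <- lapply(seq_along(feats), function(f) {
    r <- spatial_correlation(fit_test$group_beta[, f],
                             fit_reference$group_beta[, f], mask)
    bt_len <- threshold_map(fit_test$p[, f], alpha_lenient, "none", mask)
    br_len <- threshold_map(fit_reference$p[, f], alpha_lenient, "none", mask)
    bt_fwe <- threshold_map(fit_test$p[, f], alpha_fwe, "bonferroni_fwe", mask)
    br_fwe <- threshold_map(fit_reference$p[, f], alpha_fwe, "bonferroni_fwe", mask)
    pv_len <- ppv_npv(bt_len, br_len, mask)
    pv_fwe <- ppv_npv(bt_fwe, br_fwe, mask)
    tibble::tibble(
      feature = feats[f],
      spatial_r = r$r,
      ppv_lenient = pv_len$ppv, npv_lenient = pv_len$npv,
      ppv_fwe = pv_fwe$ppv, npv_fwe = pv_fwe$npv,
      n_pos_test_lenient = sum(bt_len), n_pos_ref_lenient = sum(br_len)
    )
  })
  features <- dplyr::bind_rows(rows)
  bin_test <- vapply(seq_along(feats), function(f) {
    threshold_map(fit_test$p[, f], alpha_lenient, "none", mask)
  }, logical(nrow(fit_test$t)))
  bin_ref <- vapply(seq_along(feats), function(f) {
    threshold_map(fit_reference$p[, f], alpha_lenient, "none", mask)
  }, logical(nrow(fit_reference$t)))
  cum_test <- cumulative_map(bin_test)
  cum_ref <- cumulative_map(bin_ref)
  cum_r <- spatial_correlation(as.numeric(cum_test), as.numeric(cum_ref), mask)
  structure(
    list(features = features,
         cumulative = list(test = cum_test, reference = cum_ref,
                           spatial_r = cum_r$r, flag = cum_r$flag),
         alpha_lenient = alpha_lenient, alpha_fwe = alpha_fwe,
         mask = mask),
    class = "encoding_comparison"
  )
}

#' @export
print.encoding_comparison <- function(x, ...) {
  cat("<encoding_comparison>\n")
  cat(sprintf("  features: %d  mean spatial r: %.3f  cumulative-map r: %.3f\n",
              nrow(x$features), mean(x$features$spatial_r, na.rm = TRUE),
              x$cumulative$spatial_r))
  cat(sprintf("  mean PPV %.3f / NPV %.3f (p < %g unc.); PPV %.3f / NPV %.3f (FWE %g)\n",
              mean(x$features$ppv_lenient, na.rm = TRUE),
              mean(x$features$npv_lenient, na.rm = TRUE), x$alpha_lenient,
              mean(x$features$ppv_fwe, na.rm = TRUE),
              mean(x$features$npv_fwe, na.rm = TRUE), x$alpha_fwe))
  invisible(x)
}

#' @rdname tidy.rating_panel
#' @export
tidy.encoding_comparison <- function(x, ...) x$features

#' @rdname tidy.rating_panel
#' @export
glance.encoding_comparison <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$features),
    mean_spatial_r = mean(x$features$spatial_r, na.rm = TRUE),
    mean_ppv_lenient = mean(x$features$ppv_lenient, na.rm = TRUE),
    mean_npv_lenient = mean(x$features$npv_lenient, na.rm = TRUE),
    mean_ppv_fwe = mean(x$features$ppv_fwe, na.rm = TRUE),
    mean_npv_fwe = mean(x$features$npv_fwe, na.rm = TRUE),
    cumulative_r = x$cumulative$spatial_r
  )
}

#' Per-feature neural-similarity bars
#'
#' Bar plot of per-feature spatial correlations between the two stimulus
#' models' unthresholded group beta maps, with PPVs overlaid as points.
#'
#' @param object An `encoding_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.encoding_comparison <- function(object, ...) {
  df <- object$features
  df$feature <- factor(df$feature,
                       levels = df$feature[order(df$spatial_r)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$spatial_r), fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$ppv_lenient), colour = "darkred",
                        na.rm = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "Spatial r of group betas (bars) / lenient PPV (points)",
                  x = NULL,
                  title = "Machine vs human neural representation similarity") +
    ggplot2::theme_minimal()
}

#' Write an encoding comparison to disk
#'
#' Per-feature table as TSV; global summary (including the cumulative-map
#' correlation) as JSON.
#'
#' @param comparison An `encoding_comparison`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_encoding_comparison <- function(comparison, dir, prefix = "encoding") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_features.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_summary.json"))
  readr::write_tsv(comparison$features, p1, progress = FALSE)
  jsonlite::write_json(as.list(glance(comparison)), p2,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(c(p1, p2))
}
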