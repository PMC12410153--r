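#' Full rating-agreement report
#'
#' Stage-1 analysis: per-feature machine-vs-human agreement benchmarked
#' against leave-one-out intersubject consistency and split-group consistency,
#' with Fisher-z Welch comparisons and exceedance fractions, plus the pooled
#' correlation of machine means against human means over all feature-item
#' pairs.
#'
#' @param human A human `rating_panel` (already on the analysis scale and
#'   with unperceived features excluded, see
#'   [exclude_unperceived_features()]).
#' @param machine A `machine_rating_set` or a precomputed
#'   `mean_rating_matrix` of machine ratings on the same scale.
#' @param group_size Raters per group for split-group consistency.
#' @param min_pairs Minimum complete item pairs per correlation.
#' @return An `agreement_report`: list with `features` (per-feature tibble),
#'   `comparisons` (Welch tests tibble), `summary` (named list of scalars).
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
agreement_report <- function(human, machine, group_size = 5L, min_pairs = 3L) {
  stopifnot(inherits(human, "rating_panel"))
  machine_mean <- if (inherits(machine, "machine_rating_set")) {
    mean_over_rounds(machine)
  } else if (inherits(machine, "mean_rating_matrix")) {
    machine
  } else {
    abort("`machine` must be a machine_rating_set or mean_rating_matrix.",
          class = "sc_parameter_error")
  }
  human_mean <- mean_over_raters(human)

  agr <- feature_agreement(machine_mean, human_mean, min_pairs = min_pairs)
  isc <- intersubject_consistency(human, min_pairs = min_pairs)
  grp <- group_consistency(human, group_size = group_size,
                           min_pairs = min_pairs)

  features <- agr |>
    dplyr::left_join(dplyr::select(isc, "feature",
                                   intersubject_consistency = "consistency"),
                     by = "feature") |>
    dplyr::left_join(dplyr::select(grp, "feature",
                                   group_consistency = "consistency"),
                     by = "feature")

  z_agr <- fisher_z(features$agreement)
  z_isc <- fisher_z(features$intersubject_consistency)
  z_grp <- fisher_z(features$group_consistency)
  comparisons <- dplyr::bind_rows(
    dplyr::mutate(compare_agreement_sets(z_agr, z_isc),
                  comparison = "agreement_vs_intersubject", .before = 1),
    dplyr::mutate(compare_agreement_sets(z_agr, z_grp),
                  comparison = "agreement_vs_group", .before = 1)
  )

  ex_isc <- exceedance_fraction(features$agreement,
                                features$intersubject_consistency)
  ex_grp <- exceedance_fraction(features$agreement,
                                features$group_consistency)

  al <- align_mean_matrices(machine_mean, human_mean)
  pooled <- .pearson_flagged(as.vector(al$a$values), as.vector(al$b$values))

  summary <- list(
    n_features = nrow(features),
    group_size = group_size,
    mean_agreement = mean(features$agreement, na.rm = TRUE),
    mean_intersubject_consistency =
      mean(features$intersubject_consistency, na.rm = TRUE),
    mean_group_consistency = mean(features$group_consistency, na.rm = TRUE),
    overall_r = pooled$r,
    exceed_intersubject = ex_isc$fraction,
    exceed_group = ex_grp$fraction
  )
  structure(list(features = features, comparisons = comparisons,
                 summary = summary),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  s <- x$summary
  cat("<agreement_report>\n")
  cat(sprintf("  features: %d   overall r (pooled cells): %.3f\n",
              s$n_features, s$overall_r))
  cat(sprintf("  mean agreement: %.3f | intersubject: %.3f | group-of-%d: %.3f\n",
              s$mean_agreement, s$mean_intersubject_consistency,
              s$group_size, s$mean_group_consistency))
  cat(sprintf("  agreement > intersubject for %.0f%% of features; > group for %.0f%%\n",
              100 * s$exceed_intersubject, 100 * s$exceed_group))
  invisible(x)
}

#' Tidy methods for agreement reports
#'
#' `tidy()` returns the per-feature table; `glance()` a one-row summary.
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @export
tidy.agreement_report <- function(x, ...) x$features

#' @rdname tidy.agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' Agreement-vs-consistency scatter
#'
#' Per-feature machine agreement against the chosen human reliability
#' benchmark, with the identity line; points above the line are features the
#' machine annotates more reliably than the benchmark.
#'
#' @param object An `agreement_report`.
#' @param benchmark `"intersubject"` or `"group"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.agreement_report <- function(object,
                                      benchmark = c("intersubject", "group"),
                                      ...) {
  benchmark <- match.arg(benchmark)
  col <- if (benchmark == "intersubject") "intersubject_consistency" else
    "group_consistency"
  df <- dplyr::filter(object$features,
                      !is.na(.data$agreement), !is.na(.data[[col]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[col]], y = .data$agreement)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = sprintf("Human %s consistency", benchmark),
      y = "Machine agreement with human average",
      title = "Per-feature agreement vs human reliability benchmark"
    ) +
    ggplot2::theme_minimal()
}

#' Write an agreement report to disk
#'
#' Per-feature table as TSV, global summary and comparisons as JSON, scatter
#' data (agreement vs both benchmarks) as TSV.
#'
#' @param report An `agreement_report`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_agreement_report <- function(report, dir, prefix = "agreement") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_features.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_summary.json"))
  p3 <- file.path(dir, paste0(prefix, "_scatter.tsv"))
  readr::write_tsv(report$features, p1, progress = FALSE)
  jsonlite::write_json(
    list(summary = report$summary,
         comparisons = report$comparisons),
    p2, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  scatter <- dplyr::select(report$features, "feature", "agreement",
                           "intersubject_consistency", "group_consistency")
  readr::write_tsv(scatter, p3, progress = FALSE)
  invisible(c(p1, p2, p3))
}
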