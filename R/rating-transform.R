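#' Rescale ratings onto a target scale
#'
#' Affinely maps every non-missing rating from the panel's declared scale onto
#' `to`, e.g. from the 0-100 collection scale onto the 0-10 analysis scale.
#' Missing values are preserved and the map is the identity when the scales
#' already agree.
#'
#' @param x A `rating_panel`, `machine_rating_set`, or `mean_rating_matrix`.
#' @param to Target `(lo, hi)` scale, default `c(0, 10)`.
#' @return An object of the same class on the target scale.
#' @examples
#' arr <- array(c(0, 55, 100), dim = c(3, 1, 1),
#'              dimnames = list(paste0("i", 1:3), "f", "r1"))
#' p <- rating_panel(arr, scale = c(0, 100))
#' scale_ratings(p, c(0, 10))$ratings[, 1, 1]
#' @export
scale_ratings <- function(x, to = c(0, 10)) UseMethod("scale_ratings")

.rescale_values <- function(v, from, to) {
  from <- .check_scale(from)
  to <- .check_scale(to)
  (v - from[1]) / (from[2] - from[1]) * (to[2] - to[1]) + to[1]
}

#' @export
scale_ratings.rating_panel <- function(x, to = c(0, 10)) {
  x$ratings <- .rescale_values(x$ratings, x$scale, to)
  x$scale <- .check_scale(to)
  x
}

#' @export
scale_ratings.machine_rating_set <- function(x, to = c(0, 10)) {
  x$ratings <- .rescale_values(x$ratings, x$scale, to)
  x$scale <- .check_scale(to)
  x
}

#' @export
scale_ratings.mean_rating_matrix <- function(x, to = c(0, 10)) {
  x$values <- .rescale_values(x$values, x$scale, to)
  x$scale <- .check_scale(to)
  x
}

#' Average a rater pool into a mean rating matrix
#'
#' Per-(item, feature) mean over the raters that provided a rating; a cell is
#' missing only when every rater is missing. This is the population-average
#' reference the machine annotator is compared against.
#'
#' @param panel A `rating_panel`.
#' @return A [mean_rating_matrix()].
#' @export
mean_over_raters <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  .mean_over_axis3(panel$ratings, panel$scale)
}

#' Average a machine annotator's collection rounds
#'
#' Per-(item, feature) mean over the rounds in which the annotator returned a
#' rating. Items that failed in every round (refusals) are excluded from the
#' result; their identifiers are kept in the `failed_items` attribute.
#'
#' @param machine A `machine_rating_set`.
#' @return A [mean_rating_matrix()] without the failed items.
#' @export
mean_over_rounds <- function(machine) {
  stopifnot(inherits(machine, "machine_rating_set"))
  keep <- setdiff(dimnames(machine$ratings)[[1]], machine$failed_items)
  arr <- machine$ratings[keep, , , drop = FALSE]
  out <- .mean_over_axis3(arr, machine$scale)
  attr(out, "failed_items") <- machine$failed_items
  out
}

.mean_over_axis3 <- function(arr, scale) {
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  n <- rowSums(!is.na(m))
  s <- rowSums(m, na.rm = TRUE)
  vals <- ifelse(n > 0, s / n, NA_real_)
  values <- matrix(vals, d[1], d[2],
                   dimnames = dimnames(arr)[1:2])
  counts <- matrix(as.integer(n), d[1], d[2],
                   dimnames = dimnames(arr)[1:2])
  mean_rating_matrix(values, counts, scale = scale)
}

#' Exclude features the human pool did not perceive
#'
#' Drops features whose human mean rating is the scale minimum for every item
#' (the feature was not present in the stimulus at all) or whose mean has zero
#' variance across items (Pearson correlation with it is undefined). The
#' dropped features and the reason are recorded in the `excluded_features`
#' attribute of the returned panel.
#'
#' @param panel A human `rating_panel`.
#' @return The panel reduced to the retained features; see
#'   [excluded_features()] for the report.
#' @export
exclude_unperceived_features <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  mm <- mean_over_raters(panel)
  lo <- panel$scale[1]
  feats <- colnames(mm$values)
  all_min <- apply(mm$values, 2L, function(v) all(!is.na(v) & v == lo))
  zero_var <- apply(mm$values, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || sd(v) == 0
  })
  reason <- dplyr::case_when(
    all_min ~ "not_perceived",
    zero_var ~ "zero_variance",
    TRUE ~ NA_character_
  )
  drop <- !is.na(reason)
  report <- tibble::tibble(feature = feats[drop], reason = reason[drop])
  out <- panel
  out$ratings <- panel$ratings[, !drop, , drop = FALSE]
  attr(out, "excluded_features") <- report
  out
}

#' @rdname exclude_unperceived_features
#' @param x A panel returned by [exclude_unperceived_features()].
#' @export
excluded_features <- function(x) {
  attr(x, "excluded_features") %||%
    tibble::tibble(feature = character(), reason = character())
}

#' Restrict two mean rating matrices to shared items and features
#'
#' Aligns a machine mean matrix and a human mean matrix on their common item
#' set (e.g. after dropping the machine's failed items). The feature sets must
#' match exactly; a mismatch is an alignment error.
#'
#' @param a,b `mean_rating_matrix` objects.
#' @return A list with the two aligned matrices.
#' @export
align_mean_matrices <- function(a, b) {
  stopifnot(inherits(a, "mean_rating_matrix"), inherits(b, "mean_rating_matrix"))
  if (!setequal(colnames(a$values), colnames(b$values))) {
    abort("Feature sets differ between the two mean matrices.",
          class = "sc_alignment_error")
  }
  items <- intersect(rownames(a$values), rownames(b$values))
  if (length(items) < 3L) {
    abort("Fewer than 3 shared items after alignment.",
          class = "sc_alignment_error")
  }
  feats <- colnames(a$values)
  list(
    a = mean_rating_matrix(a$values[items, feats, drop = FALSE],
                           a$n_contributing[items, feats, drop = FALSE],
                           a$scale),
    b = mean_rating_matrix(b$values[items, feats, drop = FALSE],
                           b$n_contributing[items, feats, drop = FALSE],
                           b$scale)
  )
}
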