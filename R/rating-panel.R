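#' Multi-rater annotation panels
#'
#' A `rating_panel` holds bounded-scale ratings of a set of items on a set of
#' social features by a pool of raters, as an item x feature x rater array
#' with explicit missingness. A `machine_rating_set` is the analogous
#' container for a stochastic machine annotator queried over repeated
#' collection rounds (item x feature x round); items the annotator refused in
#' every round are flagged as failed. Both are usually built from a long
#' table with [as_rating_panel()] or read from CSV with [read_rating_table()].
#'
#' @param ratings A 3-way numeric array (item x feature x rater/round) with
#'   dimnames on all three axes. `NA` encodes a missing rating.
#' @param scale Numeric `(lo, hi)` bounds of the rating scale.
#' @param modality Free-text label for the stimulus modality
#'   (`"image"`, `"video"`, ...).
#' @return An object of class `rating_panel` or `machine_rating_set`.
#' @examples
#' arr <- array(c(1, 5, 3, 7, 2, 6), dim = c(1, 2, 3),
#'              dimnames = list("clip1", c("talking", "crying"), paste0("r", 1:3)))
#' p <- rating_panel(arr, scale = c(0, 10))
#' dim(p$ratings)
#' @export
rating_panel <- function(ratings, scale = c(0, 10), modality = "other") {
  .validate_axes(ratings)
  scale <- .check_scale(scale)
  .check_bounds(ratings, scale)
  structure(
    list(ratings = ratings, scale = scale, modality = modality),
    class = "rating_panel"
  )
}

#' @rdname rating_panel
#' @export
machine_rating_set <- function(ratings, scale = c(0, 10), modality = "other") {
  .validate_axes(ratings)
  scale <- .check_scale(scale)
  .check_bounds(ratings, scale)
  # an item missing in every round for every feature was refused outright
  failed <- apply(is.na(ratings), 1L, all)
  structure(
    list(ratings = ratings, scale = scale, modality = modality,
         failed_items = dimnames(ratings)[[1]][failed]),
    class = "machine_rating_set"
  )
}

.validate_axes <- function(ratings) {
  if (!is.array(ratings) || length(dim(ratings)) != 3L) {
    abort("`ratings` must be a 3-way array (item x feature x rater/round).",
          class = "sc_parameter_error")
  }
  dn <- dimnames(ratings)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1)))) {
    abort("`ratings` must carry dimnames on all three axes.",
          class = "sc_parameter_error")
  }
  for (ax in seq_along(dn)) {
    if (anyDuplicated(dn[[ax]])) {
      abort(sprintf("Duplicate identifiers on axis %d of the rating array.", ax),
            class = "sc_integrity_error")
    }
  }
  invisible(ratings)
}

.check_bounds <- function(ratings, scale) {
  v <- ratings[!is.na(ratings)]
  if (length(v) && (min(v) < scale[1] || max(v) > scale[2])) {
    abort(sprintf("Ratings outside the declared scale [%g, %g].",
                  scale[1], scale[2]),
          class = "sc_integrity_error")
  }
  invisible(ratings)
}

#' Build a rating panel from a long table
#'
#' @param data A data frame in long format with one row per observed rating.
#' @param item,feature,rater,rating Column names (strings) holding the item
#'   identifier, feature name, rater (or collection-round) identifier, and the
#'   numeric rating.
#' @param scale Numeric `(lo, hi)` rating-scale bounds.
#' @param modality Stimulus modality label.
#' @param kind `"rater"` builds a [rating_panel()] (human pool); `"round"`
#'   builds a [machine_rating_set()] whose third axis is collection rounds.
#' @return A `rating_panel` or `machine_rating_set`.
#' @details Duplicate (item, feature, rater) rows are an integrity error:
#'   a cell of the panel must come from a single observation.
#' @export
as_rating_panel <- function(data, item = "item_id", feature = "feature",
                            rater = "rater_id", rating = "rating",
                            scale = c(0, 10), modality = "other",
                            kind = c("rater", "round")) {
  kind <- match.arg(kind)
  miss <- setdiff(c(item, feature, rater, rating), names(data))
  if (length(miss)) {
    abort(paste0("Missing mandatory column(s): ", paste(miss, collapse = ", ")),
          class = "sc_schema_error")
  }
  it <- as.character(data[[item]])
  ft <- as.character(data[[feature]])
  rt <- as.character(data[[rater]])
  val <- data[[rating]]
  if (!is.numeric(val)) {
    abort("`rating` column must be numeric; use read_rating_table() for raw CSVs.",
          class = "sc_schema_error")
  }
  key <- paste(it, ft, rt, sep = "\r")
  if (anyDuplicated(key)) {
    abort("Duplicate (item, feature, rater) rows in the rating table.",
          class = "sc_integrity_error")
  }
  items <- unique(it)
  feats <- unique(ft)
  rats <- unique(rt)
  arr <- array(NA_real_, dim = c(length(items), length(feats), length(rats)),
               dimnames = list(items, feats, rats))
  arr[cbind(match(it, items), match(ft, feats), match(rt, rats))] <- val
  if (kind == "rater") {
    rating_panel(arr, scale = scale, modality = modality)
  } else {
    machine_rating_set(arr, scale = scale, modality = modality)
  }
}

#' @export
print.rating_panel <- function(x, ...) {
  d <- dim(x$ratings)
  cat(sprintf("<rating_panel> %d items x %d features x %d raters on [%g, %g]\n",
              d[1], d[2], d[3], x$scale[1], x$scale[2]))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$ratings))))
  invisible(x)
}

#' @export
print.machine_rating_set <- function(x, ...) {
  d <- dim(x$ratings)
  cat(sprintf("<machine_rating_set> %d items x %d features x %d rounds on [%g, %g]\n",
              d[1], d[2], d[3], x$scale[1], x$scale[2]))
  cat(sprintf("  failed items (refused in all rounds): %d\n",
              length(x$failed_items)))
  invisible(x)
}

#' @export
dim.rating_panel <- function(x) dim(x$ratings)

#' @export
dim.machine_rating_set <- function(x) dim(x$ratings)

#' Tidy a rating panel into a long tibble
#'
#' @param x A `rating_panel` or `machine_rating_set`.
#' @param drop_missing Drop rows for missing cells (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `item_id`, `feature`, `rater_id` (or
#'   `round`), and `rating`.
#' @export
tidy.rating_panel <- function(x, drop_missing = TRUE, ...) {
  .tidy_panel(x, axis3 = "rater_id", drop_missing = drop_missing)
}

#' @rdname tidy.rating_panel
#' @export
tidy.machine_rating_set <- function(x, drop_missing = TRUE, ...) {
  .tidy_panel(x, axis3 = "round", drop_missing = drop_missing)
}

.tidy_panel <- function(x, axis3, drop_missing) {
  dn <- dimnames(x$ratings)
  out <- tibble::tibble(
    item_id = rep(dn[[1]], times = length(dn[[2]]) * length(dn[[3]])),
    feature = rep(rep(dn[[2]], each = length(dn[[1]])), times = length(dn[[3]])),
    !!axis3 := rep(dn[[3]], each = length(dn[[1]]) * length(dn[[2]])),
    rating = as.vector(x$ratings)
  )
  if (drop_missing) out <- dplyr::filter(out, !is.na(.data$rating))
  out
}

#' Mean rating matrix
#'
#' Item x feature matrix of mean ratings (over raters or rounds), with the
#' count of contributing observations per cell. Produced by
#' [mean_over_raters()] and [mean_over_rounds()].
#'
#' @param values Item x feature numeric matrix with dimnames.
#' @param n_contributing Integer matrix of the same shape: how many
#'   raters/rounds contributed to each mean.
#' @param scale `(lo, hi)` rating-scale bounds.
#' @return A `mean_rating_matrix`.
#' @export
mean_rating_matrix <- function(values, n_contributing, scale = c(0, 10)) {
  scale <- .check_scale(scale)
  stopifnot(is.matrix(values), identical(dim(values), dim(n_contributing)))
  if (any(!is.na(values) & n_contributing < 1L)) {
    abort("Non-missing mean with zero contributing observations.",
          class = "sc_integrity_error")
  }
  structure(list(values = values, n_contributing = n_contributing,
                 scale = scale),
            class = "mean_rating_matrix")
}

#' @export
print.mean_rating_matrix <- function(x, ...) {
  cat(sprintf("<mean_rating_matrix> %d items x %d features on [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$scale[1], x$scale[2]))
  invisible(x)
}

#' @export
dim.mean_rating_matrix <- function(x) dim(x$values)

#' @rdname tidy.rating_panel
#' @export
tidy.mean_rating_matrix <- function(x, drop_missing = TRUE, ...) {
  out <- tibble::tibble(
    item_id = rep(rownames(x$values), times = ncol(x$values)),
    feature = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    n_contributing = as.vector(x$n_contributing)
  )
  if (drop_missing) out <- dplyr::filter(out, !is.na(.data$value))
  out
}
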