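#' Read a long rating table from CSV
#'
#' Reads a long-format rating CSV (one row per observed rating) and builds a
#' [rating_panel()] or [machine_rating_set()]. Rows whose rating does not
#' parse as a number are dropped with a warning that reports the count;
#' duplicate (item, feature, rater) rows abort with an integrity error.
#'
#' @param path Path to a CSV file with a header.
#' @param schema Named list mapping the roles `item`, `feature`, `rater`,
#'   `rating` to column names in the file. Defaults to
#'   `item_id`/`feature`/`rater_id` (or `round`)/`rating`.
#' @param scale `(lo, hi)` bounds the ratings were collected on.
#' @param modality Stimulus modality label; if the file has a `modality`
#'   column its first value is used instead.
#' @param kind `"rater"` for a human pool, `"round"` for a multi-round
#'   machine annotator.
#' @return A `rating_panel` or `machine_rating_set`.
#' @seealso [write_rating_table()]
#' @export
read_rating_table <- function(path, schema = NULL, scale = c(0, 100),
                              modality = "other",
                              kind = c("rater", "round")) {
  kind <- match.arg(kind)
  default_rater <- if (kind == "rater") "rater_id" else "round"
  schema <- utils::modifyList(
    list(item = "item_id", feature = "feature",
         rater = default_rater, rating = "rating"),
    as.list(schema %||% list())
  )
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  miss <- setdiff(unlist(schema), names(raw))
  if (length(miss)) {
    abort(paste0("CSV is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")),
          class = "sc_schema_error")
  }
  val <- suppressWarnings(as.numeric(raw[[schema$rating]]))
  bad <- is.na(val)
  if (any(bad)) {
    warn(sprintf("Dropped %d row(s) with unparseable or empty ratings.", sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
    val <- val[!bad]
  }
  if ("modality" %in% names(raw) && nrow(raw)) modality <- raw$modality[[1]]
  df <- tibble::tibble(
    item_id = raw[[schema$item]],
    feature = raw[[schema$feature]],
    rater_id = raw[[schema$rater]],
    rating = val
  )
  as_rating_panel(df, item = "item_id", feature = "feature",
                  rater = "rater_id", rating = "rating",
                  scale = scale, modality = modality, kind = kind)
}

#' Write a rating panel to a long CSV
#'
#' Writes the long-format CSV that [read_rating_table()] reads back
#' cell-for-cell (missing cells are omitted).
#'
#' @param x A `rating_panel` or `machine_rating_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rating_table <- function(x, path) {
  long <- tidy(x, drop_missing = TRUE)
  long$modality <- x$modality
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Write a panel summary as TSV
#'
#' Per-feature summary (mean, sd, missingness) of a panel, written as TSV.
#'
#' @param x A `rating_panel` or `machine_rating_set`.
#' @param path Output TSV path.
#' @return The summary tibble, invisibly.
#' @export
write_panel_summary <- function(x, path) {
  long <- tidy(x, drop_missing = FALSE)
  out <- long |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      mean_rating = mean(.data$rating, na.rm = TRUE),
      sd_rating = sd(.data$rating, na.rm = TRUE),
      frac_missing = mean(is.na(.data$rating)),
      .groups = "drop"
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
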