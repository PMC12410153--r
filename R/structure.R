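#' Feature-by-feature correlation matrix of mean ratings
#'
#' Pairwise Pearson correlations between every pair of feature rating vectors
#' across items (pairwise-complete). The matrix summarises the
#' representational structure of the annotations; comparing the machine's
#' matrix with the human one is the stage-2 analysis.
#'
#' @param mean_ratings A `mean_rating_matrix` (or plain item x feature
#'   matrix).
#' @param min_pairs Minimum complete item pairs per feature pair.
#' @return A symmetric F x F correlation matrix with unit diagonal and
#'   feature dimnames.
#' @export
feature_correlation_matrix <- function(mean_ratings, min_pairs = 3L) {
  vals <- if (inherits(mean_ratings, "mean_rating_matrix")) {
    mean_ratings$values
  } else {
    as.matrix(mean_ratings)
  }
  if (nrow(vals) < 3L) {
    abort("At least 3 items are required for a feature correlation matrix.",
          class = "sc_insufficient_data_error")
  }
  sds <- apply(vals, 2L, sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0)) {
    abort(paste0("Zero-variance feature(s) reached correlation stage: ",
                 paste(colnames(vals)[is.na(sds) | sds == 0], collapse = ", "),
                 ". Exclude them upstream."),
          class = "sc_integrity_error")
  }
  C <- suppressWarnings(cor(vals, use = "pairwise.complete.obs"))
  # enforce the min-pairs rule cor() does not apply
  if (anyNA(vals)) {
    ok <- !is.na(vals)
    npair <- crossprod(ok)
    C[npair < min_pairs] <- NA_real_
  }
  diag(C) <- 1
  C
}

.check_square_sym <- function(A, name = "matrix") {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    abort(sprintf("`%s` must be square.", name), class = "sc_parameter_error")
  }
  if (max(abs(A - t(A)), na.rm = TRUE) > 1e-8) {
    abort(sprintf("`%s` must be symmetric.", name),
          class = "sc_parameter_error")
  }
  invisible(A)
}

#' Similarity of two feature correlation matrices
#'
#' Pearson correlation between the strict upper triangles (diagonal excluded)
#' of two correlation matrices over the same ordered feature set: F(F-1)/2
#' paired entries.
#'
#' @param A,B Symmetric correlation matrices with matching dimnames.
#' @return The scalar correlation.
#' @export
matrix_similarity <- function(A, B) {
  .check_square_sym(A, "A"); .check_square_sym(B, "B")
  if (!identical(dim(A), dim(B)) ||
      (!is.null(rownames(A)) && !is.null(rownames(B)) &&
       !identical(rownames(A), rownames(B)))) {
    abort("A and B must share the same feature set and order.",
          class = "sc_alignment_error")
  }
  ut <- upper.tri(A)
  cor(A[ut], B[ut], use = "complete.obs")
}

#' Mantel permutation test for matrix association
#'
#' Tests whether two symmetric feature-similarity matrices are more alike
#' than chance. The statistic is [matrix_similarity()] (Pearson r of the
#' strict upper triangles). The null distribution is built by applying one
#' random permutation jointly to the rows and columns of `B`; the one-sided
#' p-value is `(#\{null r >= observed\} + 1) / (n_permutations + 1)`.
#'
#' @param A,B Symmetric matrices of equal size (F >= 3).
#' @param n_permutations Number of random permutations (default 9999).
#' @param seed Optional integer seed for reproducibility.
#' @param exhaustive If `TRUE` (only for F <= 7), enumerate all F!
#'   permutations instead; p is then the exact proportion of permutations
#'   (identity included) with null r >= observed.
#' @return A one-row tibble: `statistic`, `p_value`, `n_permutations`,
#'   `method`.
#' @export
mantel_test <- function(A, B, n_permutations = 9999L, seed = NULL,
                        exhaustive = FALSE) {
  .check_square_sym(A, "A"); .check_square_sym(B, "B")
  f <- nrow(A)
  if (f < 3L) {
    abort("Mantel test requires matrices of size >= 3.",
          class = "sc_parameter_error")
  }
  if (!identical(dim(A), dim(B))) {
    abort("A and B must have equal size.", class = "sc_alignment_error")
  }
  ut <- which(upper.tri(A), arr.ind = TRUE)
  ii <- ut[, 1L]; jj <- ut[, 2L]
  a <- A[upper.tri(A)]
  b <- B[upper.tri(B)]
  ac <- a - mean(a)
  ssa <- sum(ac^2)
  # the multiset of off-diagonal entries of B is invariant under joint
  # row/column permutation, so centre and scale of the null draws are fixed
  ssb <- sum((b - mean(b))^2)
  den <- sqrt(ssa * ssb)
  r_obs <- sum(ac * b) / den
  Bv <- as.vector(B)

  perm_r <- function(p) {
    bp <- Bv[p[ii] + (p[jj] - 1L) * f]
    sum(ac * bp) / den
  }

  if (exhaustive) {
    if (f > 7L) {
      abort("Exhaustive enumeration is limited to F <= 7.",
            class = "sc_parameter_error")
    }
    perms <- .all_permutations(f)
    null_r <- vapply(perms, perm_r, numeric(1))
    p <- mean(null_r >= r_obs - 1e-12)
    return(tibble::tibble(statistic = r_obs, p_value = p,
                          n_permutations = length(perms),
                          method = "exhaustive"))
  }
  if (n_permutations < 1L) {
    abort("`n_permutations` must be >= 1.", class = "sc_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (k in seq_len(n_permutations)) {
    if (perm_r(sample.int(f)) >= r_obs - 1e-12) count <- count + 1L
  }
  tibble::tibble(
    statistic = r_obs,
    p_value = (count + 1) / (n_permutations + 1),
    n_permutations = as.integer(n_permutations),
    method = "monte_carlo"
  )
}

.all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Write Mantel results as JSON
#'
#' @param result Tibble returned by [mantel_test()].
#' @param path Output JSON path.
#' @param seed Seed used, recorded alongside the result.
#' @return `path`, invisibly.
#' @export
write_mantel_json <- function(result, path, seed = NULL) {
  jsonlite::write_json(
    c(as.list(result), list(seed = seed)),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}
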