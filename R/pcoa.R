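#' Principal coordinate analysis of a feature correlation matrix
#'
#' Classical multidimensional scaling of the correlation-derived distance
#' d_ij = 1 - r_ij: the squared-distance matrix is Gower double-centred
#' (B = -1/2 J D^2 J with J the centering projector) and eigendecomposed;
#' coordinates ("loadings" of the features on each component) are the
#' eigenvectors scaled by the square root of their eigenvalues, for the k
#' largest positive eigenvalues. Since 1 - r is not guaranteed Euclidean,
#' negative eigenvalues can occur; they are dropped and counted.
#'
#' @param C Symmetric feature correlation matrix (complete, unit diagonal).
#' @param k Number of components to retain (default: all positive
#'   eigenvalues; capped at F - 1). If fewer positive eigenvalues exist than
#'   requested, the result is truncated with a warning.
#' @param distance How to turn correlations into distances; only
#'   `"one_minus_r"` is provided but the choice is isolated here.
#' @return A `pcoa_result`: list with `loadings` (F x k, feature rownames),
#'   `eigenvalues` (descending, the retained k), `variance_fraction`
#'   (per-component share of the positive-eigenvalue total),
#'   `n_negative_eigenvalues`, `all_eigenvalues`.
#' @examples
#' C <- diag(4)
#' C[1, 2] <- C[2, 1] <- 0.9
#' rownames(C) <- colnames(C) <- paste0("f", 1:4)
#' res <- pcoa(C, k = 2)
#' res$eigenvalues
#' @export
pcoa <- function(C, k = NULL, distance = c("one_minus_r")) {
  distance <- match.arg(distance)
  .check_square_sym(C, "C")
  if (anyNA(C)) {
    abort("PCoA requires a complete correlation matrix.",
          class = "sc_parameter_error")
  }
  f <- nrow(C)
  D <- 1 - C
  J <- diag(f) - matrix(1 / f, f, f)
  B <- -0.5 * J %*% (D * D) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eg$values
  tol <- max(abs(ev)) * 1e-12
  n_pos <- sum(ev > tol)
  n_neg <- sum(ev < -tol)
  k_req <- k %||% min(n_pos, f - 1L)
  if (k_req > f - 1L) {
    abort("`k` must be at most F - 1.", class = "sc_parameter_error")
  }
  k_eff <- min(k_req, n_pos)
  if (k_eff < k_req) {
    warn(sprintf("Only %d positive eigenvalues available; truncating k from %d.",
                 n_pos, k_req))
  }
  vals <- ev[seq_len(k_eff)]
  vecs <- eg$vectors[, seq_len(k_eff), drop = FALSE]
  loadings <- sweep(vecs, 2L, sqrt(vals), `*`)
  rownames(loadings) <- rownames(C)
  colnames(loadings) <- paste0("PC", seq_len(k_eff))
  structure(
    list(
      loadings = loadings,
      eigenvalues = vals,
      variance_fraction = vals / sum(ev[ev > tol]),
      n_negative_eigenvalues = n_neg,
      all_eigenvalues = ev
    ),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d features x %d components (%d negative eigenvalues dropped)\n",
              nrow(x$loadings), ncol(x$loadings), x$n_negative_eigenvalues))
  vf <- round(100 * x$variance_fraction[seq_len(min(8L, length(x$variance_fraction)))], 1)
  cat("  variance explained (%):", paste(vf, collapse = ", "),
      if (length(x$variance_fraction) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @rdname tidy.rating_panel
#' @export
tidy.pcoa_result <- function(x, ...) {
  tibble::tibble(
    feature = rep(rownames(x$loadings), times = ncol(x$loadings)),
    component = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings)
  )
}

#' Concordance of two PCoA loading sets
#'
#' For every pair of components (one from each ordination) the Pearson
#' correlation of feature loadings is computed across the shared feature set.
#' Absolute correlations are reported because component signs are arbitrary;
#' two-sided p-values use the t transform of r with F - 2 degrees of freedom,
#' and the significance mask applies `alpha` (default 0.001).
#'
#' @param L_a,L_b `pcoa_result` objects (or plain F x K loading matrices with
#'   feature rownames) over the same features.
#' @param alpha Significance level for the mask.
#' @param k_max Compare only the first `k_max` components of each side
#'   (default: all available in both).
#' @return A `concordance_matrix`: list with `abs_r` (K_a x K_b), `p`,
#'   `significant`, `alpha`, `n_features`.
#' @export
loading_concordance <- function(L_a, L_b, alpha = 0.001, k_max = NULL) {
  A <- if (inherits(L_a, "pcoa_result")) L_a$loadings else as.matrix(L_a)
  B <- if (inherits(L_b, "pcoa_result")) L_b$loadings else as.matrix(L_b)
  if (is.null(rownames(A)) || is.null(rownames(B)) ||
      !identical(rownames(A), rownames(B))) {
    abort("Loading matrices must share an identical ordered feature set.",
          class = "sc_alignment_error")
  }
  ka <- ncol(A); kb <- ncol(B)
  if (!is.null(k_max)) {
    if (k_max > min(ka, kb)) {
      abort("`k_max` exceeds the components available in both inputs.",
            class = "sc_parameter_error")
    }
    A <- A[, seq_len(k_max), drop = FALSE]
    B <- B[, seq_len(k_max), drop = FALSE]
    ka <- kb <- k_max
  }
  f <- nrow(A)
  R <- cor(A, B)
  tstat <- R * sqrt((f - 2) / pmax(1 - R^2, 1e-300))
  p <- 2 * pt(abs(tstat), df = f - 2, lower.tail = FALSE)
  abs_r <- abs(R)
  dimnames(abs_r) <- dimnames(p) <- list(colnames(A), colnames(B))
  structure(
    list(abs_r = abs_r, p = p, significant = p < alpha,
         alpha = alpha, n_features = f),
    class = "concordance_matrix"
  )
}

#' @export
print.concordance_matrix <- function(x, ...) {
  cat(sprintf("<concordance_matrix> %d x %d components over %d features (alpha = %g)\n",
              nrow(x$abs_r), ncol(x$abs_r), x$n_features, x$alpha))
  kd <- min(dim(x$abs_r))
  cat("  diagonal |r|:",
      paste(round(diag(x$abs_r)[seq_len(min(8L, kd))], 2), collapse = ", "),
      if (kd > 8L) "..." else "", "\n")
  invisible(x)
}

#' @rdname tidy.rating_panel
#' @export
tidy.concordance_matrix <- function(x, ...) {
  tibble::tibble(
    component_a = rep(rownames(x$abs_r), times = ncol(x$abs_r)),
    component_b = rep(colnames(x$abs_r), each = nrow(x$abs_r)),
    abs_r = as.vector(x$abs_r),
    p_value = as.vector(x$p),
    significant = as.vector(x$significant)
  )
}

#' Greedily match components between two ordinations
#'
#' Components of the two ordinations are paired one-to-one in descending
#' order of absolute loading correlation, which resolves occasional swaps of
#' near-degenerate components when judging whether a planted dimensionality
#' was recovered.
#'
#' @param x A `concordance_matrix`.
#' @param k Number of pairs to match (default: the smaller component count).
#' @return A tibble with `component_a`, `component_b`, `abs_r`, `p_value`,
#'   ordered by `component_a`'s original position.
#' @export
match_components <- function(x, k = NULL) {
  stopifnot(inherits(x, "concordance_matrix"))
  M <- x$abs_r
  k <- k %||% min(dim(M))
  avail_a <- seq_len(nrow(M))
  avail_b <- seq_len(ncol(M))
  out <- vector("list", k)
  for (step in seq_len(k)) {
    sub <- M[avail_a, avail_b, drop = FALSE]
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    ia <- avail_a[idx[1]]; ib <- avail_b[idx[2]]
    out[[step]] <- tibble::tibble(
      component_a = rownames(M)[ia], component_b = colnames(M)[ib],
      a_index = ia, b_index = ib,
      abs_r = M[ia, ib], p_value = x$p[ia, ib]
    )
    avail_a <- setdiff(avail_a, ia)
    avail_b <- setdiff(avail_b, ib)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$a_index)
}

#' Concordance heat map
#'
#' Tile plot of absolute loading correlations between machine- and
#' human-derived components; non-significant cells are blanked, mirroring the
#' usual presentation where a clear diagonal over the first few components
#' indicates a shared low-dimensional structure.
#'
#' @param object A `concordance_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concordance_matrix <- function(object, ...) {
  df <- tidy(object)
  df$abs_r_masked <- ifelse(df$significant, df$abs_r, NA_real_)
  df$component_a <- factor(df$component_a, levels = rownames(object$abs_r))
  df$component_b <- factor(df$component_b, levels = colnames(object$abs_r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component_b,
                                   y = .data$component_a,
                                   fill = .data$abs_r_masked)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey95",
                                  name = "|r|") +
    ggplot2::labs(x = "Components (B)", y = "Components (A)",
                  title = sprintf("Loading concordance (p < %g)", object$alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
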