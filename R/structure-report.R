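#' Representational-structure comparison of two annotation sources
#'
#' Stage-2 analysis in one call: feature correlation matrices for the machine
#' and human mean ratings (aligned on shared items), their upper-triangle
#' similarity with a Mantel permutation test, PCoA of each matrix, and the
#' concordance of the component loadings.
#'
#' @param machine_mean,human_mean `mean_rating_matrix` objects with matching
#'   features.
#' @param n_permutations Mantel permutations (default 10000).
#' @param seed Seed for the Mantel permutations.
#' @param k Components to retain in each PCoA (default 20).
#' @param alpha Significance level for loading concordance (default 0.001).
#' @return A `structure_report`: list with `cor_machine`, `cor_human`,
#'   `similarity` (scalar r), `mantel` (tibble), `pcoa_machine`,
#'   `pcoa_human`, `concordance`, `matched` (greedy component matching).
#' @export
structure_report <- function(machine_mean, human_mean,
                             n_permutations = 10000L, seed = NULL,
                             k = 20L, alpha = 0.001) {
  al <- align_mean_matrices(machine_mean, human_mean)
  cm <- feature_correlation_matrix(al$a)
  ch <- feature_correlation_matrix(al$b)
  k_eff <- min(k, nrow(cm) - 1L)
  mant <- mantel_test(cm, ch, n_permutations = n_permutations, seed = seed)
  pm <- pcoa(cm, k = k_eff)
  ph <- pcoa(ch, k = k_eff)
  k_avail <- min(ncol(pm$loadings), ncol(ph$loadings))
  conc <- loading_concordance(pm, ph, alpha = alpha, k_max = k_avail)
  structure(
    list(cor_machine = cm, cor_human = ch,
         similarity = mant$statistic[1], mantel = mant,
         pcoa_machine = pm, pcoa_human = ph,
         concordance = conc, matched = match_components(conc),
         seed = seed),
    class = "structure_report"
  )
}

#' @export
print.structure_report <- function(x, ...) {
  cat("<structure_report>\n")
  cat(sprintf("  correlation-matrix similarity r = %.3f (Mantel p = %.3g, %d permutations)\n",
              x$similarity, x$mantel$p_value, x$mantel$n_permutations))
  nd <- sum(diag(x$concordance$significant[
    seq_len(min(dim(x$concordance$significant))),
    seq_len(min(dim(x$concordance$significant))), drop = FALSE]))
  cat(sprintf("  significant diagonal loading correlations: %d of %d components\n",
              nd, min(dim(x$concordance$abs_r))))
  invisible(x)
}

#' @rdname tidy.rating_panel
#' @export
tidy.structure_report <- function(x, ...) tidy(x$concordance)

#' @rdname tidy.rating_panel
#' @export
glance.structure_report <- function(x, ...) {
  kd <- min(dim(x$concordance$abs_r))
  tibble::tibble(
    similarity_r = x$similarity,
    mantel_p = x$mantel$p_value,
    n_permutations = x$mantel$n_permutations,
    n_significant_diagonal =
      sum(diag(x$concordance$significant)[seq_len(kd)]),
    n_components = kd
  )
}

#' Write a structure report to disk
#'
#' Correlation matrices and PCoA loadings as TSV with feature-name headers,
#' concordance heat-map data as TSV, Mantel result as JSON.
#'
#' @param report A `structure_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_structure_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wtsv <- function(mat, name) {
    df <- tibble::as_tibble(as.data.frame(mat), rownames = "feature")
    p <- file.path(dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    p
  }
  paths <- c(paths,
             wtsv(report$cor_machine, "cor_machine.tsv"),
             wtsv(report$cor_human, "cor_human.tsv"),
             wtsv(report$pcoa_machine$loadings, "loadings_machine.tsv"),
             wtsv(report$pcoa_human$loadings, "loadings_human.tsv"))
  pc <- file.path(dir, "concordance.tsv")
  readr::write_tsv(tidy(report$concordance), pc, progress = FALSE)
  pm <- file.path(dir, "mantel.json")
  write_mantel_json(report$mantel, pm, seed = report$seed)
  invisible(c(paths, pc, pm))
}
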