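#' Run the full injury-model pipeline on a cohort
#'
#' Applies the cortex inclusion filter, trains the four injury classifiers
#' on the expression matrix, assembles and standardizes the 10-input score
#' table (with the 12 failed-repair gene-set means as supplementary
#' columns), fits the correlation PCA with deterministic orientation, fits
#' the 5-archetype model on the standardized inputs, labels and assigns
#' groups, and projects archetype scores and supplementary gene sets onto
#' the factor map.
#'
#' @param expr An [expression_matrix()] with controls designated.
#' @param meta `sample_metadata` for the biopsies.
#' @param sets Gene-set collection with the six input PBTs and twelve
#'   supplementary sets.
#' @param k Number of archetypes (default 5).
#' @param n_restarts Archetype restarts (default 10).
#' @param seed Seed for classifiers and archetypes.
#' @param cortex_threshold Percent-cortex inclusion cutoff (strict >).
#' @param classifier_args List of overrides for
#'   [train_injury_classifiers()].
#' @return An `injury_model` list: `meta` (filtered), `classifiers`,
#'   `scores` (standardized score table), `pca` (oriented), `arch`
#'   (labeled), `arch_scores`, `groups`, `factor_map` (supplementary
#'   coordinates of inputs, archetype scores and gene-set means).
#' @export
run_injury_pipeline <- function(expr, meta, sets, k = 5, n_restarts = 10,
                                seed = 1, cortex_threshold = 10,
                                classifier_args = list()) {
  check_sample_ids(expr, meta)
  meta_f <- filter_cortex(meta, threshold = cortex_threshold)
  keep <- c(meta_f$sample_id, expr$control_ids)
  expr_f <- expression_matrix(expr$values[, keep, drop = FALSE],
                              expr$control_ids)

  cls <- do.call(train_injury_classifiers,
                 c(list(expr = expr_f, meta = meta_f, seed = seed),
                   classifier_args))
  tab <- score_table(expr_f, sets, cls$probs)
  std <- standardize(tab)

  pca <- fit_pca(std)
  pca <- orient_pcs(pca, std)

  arch <- fit_archetypes(as.matrix(as.data.frame(std)[input_columns(std)]),
                         k = k, n_restarts = n_restarts, seed = seed)
  if (k == 5) arch <- label_archetypes(arch, pca)
  a_scores <- archetype_scores(arch,
                               as.matrix(as.data.frame(std)[input_columns(std)]))
  groups <- assign_group(a_scores)

  fm_inputs <- project_supplementary(pca, as.data.frame(std)[input_columns(std)])
  fm_arch <- project_supplementary(pca, a_scores)
  fm_new <- project_supplementary(pca, as.data.frame(std)[supplementary_columns(std)])
  fm <- rbind(cbind(role = "input", fm_inputs),
              cbind(role = "archetype", fm_arch),
              cbind(role = "new-gene-set", fm_new))

  structure(list(meta = meta_f, classifiers = cls, scores = std, pca = pca,
                 arch = arch, arch_scores = a_scores, groups = groups,
                 factor_map = fm),
            class = "injury_model")
}

#' @export
print.injury_model <- function(x, ...) {
  cat("injury_model\n")
  print(x$pca)
  print(x$arch)
  cat("groups:\n")
  print(table(x$groups))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions, used to compare
#' recovered archetype groups with planted states.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
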