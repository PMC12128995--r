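#' Specification of a binary molecular classifier
#'
#' The four injury classifiers are trained on the biopsies that have the
#' relevant phenotype recorded: low eGFR (eGFR <= 30 mL/min/1.73m2),
#' proteinuria positivity, fibrosis ci lesion score > 1, and atrophy ct
#' lesion score > 1. The pipeline is a univariate class-separation filter
#' followed by a ridge-penalized logistic model, cross-validated with
#' stratified folds; the model family is pluggable via `fit_fun`/`pred_fun`.
#'
#' @param label_name One of "lowGFR", "proteinuria", "ci_gt1", "ct_gt1".
#' @param n_folds Number of stratified CV folds (default 10).
#' @param n_top_features Features retained by the in-fold univariate filter.
#' @param lambda Ridge penalty for the default glmnet fit.
#' @param seed Integer seed controlling fold assignment.
#' @param fit_fun,pred_fun Optional replacement model family:
#'   `fit_fun(x, y)` -> fit, `pred_fun(fit, x)` -> probabilities.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(label_name = c("lowGFR", "proteinuria", "ci_gt1", "ct_gt1"),
                            n_folds = 10, n_top_features = 30,
                            lambda = 0.05, seed = 1,
                            fit_fun = NULL, pred_fun = NULL) {
  label_name <- match.arg(label_name)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  structure(list(label_name = label_name, n_folds = n_folds,
                 n_top_features = n_top_features, lambda = lambda,
                 seed = seed, fit_fun = fit_fun, pred_fun = pred_fun),
            class = "classifier_spec")
}

#' Derive binary labels from clinical metadata
#'
#' Label rules: lowGFR = eGFR <= 30; proteinuria = proteinuria_pos;
#' ci_gt1 = ci_score > 1; ct_gt1 = ct_score > 1. Biopsies with the
#' phenotype missing get `NA` labels: excluded from training, retained for
#' projection.
#'
#' @param meta `sample_metadata`.
#' @param spec A [classifier_spec()].
#' @return Integer vector (0/1/NA) named by sample id.
#' @export
derive_label <- function(meta, spec) {
  y <- switch(spec$label_name,
    lowGFR      = as.integer(meta$egfr <= 30),
    proteinuria = as.integer(meta$proteinuria_pos == 1),
    ci_gt1      = as.integer(meta$ci_score > 1),
    ct_gt1      = as.integer(meta$ct_score > 1)
  )
  names(y) <- meta$sample_id
  obs <- y[!is.na(y)]
  if (!length(obs)) stop("phenotype entirely missing for ", spec$label_name, call. = FALSE)
  if (length(unique(obs)) < 2) {
    stop("single-class labels for ", spec$label_name, call. = FALSE)
  }
  y
}

# stratified fold assignment, deterministic per seed
stratified_folds <- function(y, n_folds, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# two-sample t statistic per feature column; in-fold feature filter
feature_t_stats <- function(x, y) {
  i1 <- y == 1; i0 <- y == 0
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- colMeans(x[i1, , drop = FALSE]); m0 <- colMeans(x[i0, , drop = FALSE])
  v1 <- colSums(sweep(x[i1, , drop = FALSE], 2, m1)^2) / (n1 - 1)
  v0 <- colSums(sweep(x[i0, , drop = FALSE], 2, m0)^2) / (n0 - 1)
  delta <- m1 - m0
  se <- sqrt(v1 / n1 + v0 / n0)
  # zero pooled variance with separated means is perfect separation, not a
  # useless feature
  ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
}

default_fit <- function(x, y, lambda) {
  glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                 standardize = TRUE)
}

default_pred <- function(fit, x) {
  as.numeric(stats::predict(fit, newx = x, type = "response"))
}

#' Cross-validated classifier training with out-of-fold probabilities
#'
#' Stratified k-fold CV over the labeled biopsies. Inside each training
#' fold the top features are selected by absolute two-sample t statistic
#' and the model is fit on those features only, so the held-out fold never
#' influences feature selection (no leakage). The model refit on all
#' labeled data serves to project unlabeled/new biopsies; the reported AUC
#' always uses out-of-fold probabilities.
#'
#' @param features Numeric matrix, samples x features, rownames = sample ids.
#' @param labels Integer 0/1/NA vector aligned with `features` rows.
#' @param spec A [classifier_spec()].
#' @return A `classifier_result` list: `oof_probs` (labeled biopsies),
#'   `projected_probs` (all biopsies, from the full-data refit), `auc`,
#'   `folds`, `fold_features`, `final_features`, `final_fit`.
#' @export
train_cv <- function(features, labels, spec) {
  if (!all(is.finite(features))) stop("non-finite feature values", call. = FALSE)
  if (is.null(rownames(features))) stop("features need sample-id rownames", call. = FALSE)
  labeled <- which(!is.na(labels))
  y <- labels[labeled]
  if (min(table(y)) < spec$n_folds) {
    stop("each class needs at least n_folds members", call. = FALSE)
  }
  x <- features[labeled, , drop = FALSE]
  k <- min(spec$n_top_features, ncol(features))
  fold <- stratified_folds(y, spec$n_folds, spec$seed)
  fit_fun <- spec$fit_fun %||% function(x, y) default_fit(x, y, spec$lambda)
  pred_fun <- spec$pred_fun %||% default_pred

  oof <- rep(NA_real_, length(y))
  fold_features <- vector("list", spec$n_folds)
  for (f in seq_len(spec$n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) stop("degenerate fold ", f, call. = FALSE)
    ts_ <- feature_t_stats(x[tr, , drop = FALSE], y[tr])
    sel <- order(abs(ts_), decreasing = TRUE)[seq_len(k)]
    fold_features[[f]] <- colnames(x)[sel]
    fit <- fit_fun(x[tr, sel, drop = FALSE], y[tr])
    oof[fold == f] <- pred_fun(fit, x[fold == f, sel, drop = FALSE])
  }

  ts_all <- feature_t_stats(x, y)
  sel_all <- order(abs(ts_all), decreasing = TRUE)[seq_len(k)]
  final_fit <- fit_fun(x[, sel_all, drop = FALSE], y)
  projected <- pred_fun(final_fit, features[, sel_all, drop = FALSE])
  names(projected) <- rownames(features)
  names(oof) <- rownames(x)

  structure(list(oof_probs = oof, projected_probs = projected,
                 auc = auc(oof, y), folds = setNames(fold, rownames(x)),
                 fold_features = fold_features,
                 final_features = colnames(x)[sel_all],
                 final_fit = final_fit, spec = spec),
            class = "classifier_result")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outranks a random negative, with tied
#' scores counted one half.
#'
#' @param probs Numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0,1\].
#' @export
auc <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC", call. = FALSE)
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train all four injury classifiers on an expression matrix
#'
#' Convenience wrapper producing the classifier-probability columns of the
#' score table: trains lowGFR, proteinuria, ci_gt1 and ct_gt1 on the
#' biopsies with the phenotype recorded and projects every biopsy through
#' the full-data refit. For labeled biopsies the out-of-fold probability is
#' used (never a prediction from a model that saw the biopsy).
#'
#' @param expr An [expression_matrix()].
#' @param meta `sample_metadata` covering the biopsies.
#' @param n_folds,n_top_features,lambda,seed Passed to [classifier_spec()].
#' @return List: `probs` (data.frame, biopsies x 4 probability columns named
#'   lowGFR_Prob, Prot_Prob, ci_gt1_Prob, ct_gt1_Prob), `results` (the four
#'   `classifier_result` objects), `aucs`.
#' @export
train_injury_classifiers <- function(expr, meta, n_folds = 10,
                                     n_top_features = 30, lambda = 0.05,
                                     seed = 1) {
  bx <- biopsy_ids(expr)
  features <- t(expr$values[, bx, drop = FALSE])
  meta_idx <- match(bx, meta$sample_id)
  if (anyNA(meta_idx)) stop("metadata missing for some biopsies", call. = FALSE)
  m <- meta[meta_idx, , drop = FALSE]
  specs <- list(lowGFR = "lowGFR", proteinuria = "proteinuria",
                ci_gt1 = "ci_gt1", ct_gt1 = "ct_gt1")
  results <- lapply(specs, function(lbl) {
    sp <- classifier_spec(lbl, n_folds = n_folds,
                          n_top_features = n_top_features,
                          lambda = lambda, seed = seed)
    train_cv(features, derive_label(m, sp), sp)
  })
  probs <- data.frame(row.names = bx)
  col_map <- c(lowGFR = "lowGFR_Prob", proteinuria = "Prot_Prob",
               ci_gt1 = "ci_gt1_Prob", ct_gt1 = "ct_gt1_Prob")
  for (nm in names(results)) {
    p <- results[[nm]]$projected_probs[bx]
    oof <- results[[nm]]$oof_probs
    p[names(oof)] <- oof
    probs[[col_map[[nm]]]] <- p
  }
  list(probs = probs, results = results,
       aucs = vapply(results, `[[`, numeric(1), "auc"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
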