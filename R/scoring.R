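#' PBT score: mean log2 fold-change of a gene set versus controls
#'
#' The score of biopsy s for a transcript set G is
#' `mean_{g in G} (x_gs - mean_controls(x_gc))`, computed in log2 space, so
#' `2^score` is the geometric-mean fold-change of the set versus the control
#' group. Set members absent from the matrix are dropped (count recorded in
#' `attr(,"n_dropped")`).
#'
#' @param expr An [expression_matrix()].
#' @param set Character vector of probe-set ids.
#' @param control_ids Control sample ids; defaults to the matrix's own.
#' @param samples Samples to score; defaults to all non-control samples.
#' @return Named numeric vector of scores (log2 fold-change units) with
#'   attributes `fold_change` (= 2^score) and `n_dropped`.
#' @export
pbt_score <- function(expr, set, control_ids = expr$control_ids,
                      samples = biopsy_ids(expr)) {
  if (!length(control_ids)) stop("no control samples", call. = FALSE)
  present <- intersect(set, rownames(expr$values))
  n_dropped <- length(set) - length(present)
  if (!length(present)) {
    stop("no members of the set present in the expression matrix", call. = FALSE)
  }
  ctl_mean <- rowMeans(expr$values[present, control_ids, drop = FALSE])
  score <- colMeans(expr$values[present, samples, drop = FALSE] - ctl_mean)
  structure(score, fold_change = 2^score, n_dropped = n_dropped)
}

#' Assemble the per-biopsy score table
#'
#' One row per non-control biopsy. The 10 model inputs are the six PBT
#' scores (IRRAT30, IRITD3, IRITD5, DAMP, MCAT, IGT) and the four classifier
#' probabilities (lowGFR_Prob, Prot_Prob, ci_gt1_Prob, ct_gt1_Prob); the
#' twelve failed-repair gene-set means are attached as supplementary columns
#' that never enter model fitting.
#'
#' @param expr An [expression_matrix()].
#' @param sets Gene-set collection containing the six input PBTs and the
#'   twelve supplementary sets.
#' @param classifier_probs Data frame or matrix, rownames = sample ids,
#'   one column per classifier probability (values in \[0,1\]).
#' @param control_ids Control sample ids.
#' @return A `score_table` data.frame (rownames = sample ids) with
#'   attributes `input_cols` and `supplementary_cols`.
#' @export
score_table <- function(expr, sets, classifier_probs,
                        control_ids = expr$control_ids) {
  bx <- biopsy_ids(expr)
  pbt_cols <- input_pbt_names()
  sup_cols <- intersect(new_set_names(), names(sets))
  missing_sets <- setdiff(pbt_cols, names(sets))
  prob_cols <- classifier_prob_names()
  missing_probs <- setdiff(prob_cols, colnames(classifier_probs))
  if (length(missing_sets) || length(missing_probs)) {
    stop("missing model inputs: ",
         paste(c(missing_sets, missing_probs), collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(lapply(c(pbt_cols, sup_cols), function(nm) {
    sc <- pbt_score(expr, sets[[nm]], control_ids, samples = bx)
    if (length(sets[[nm]]) - attr(sc, "n_dropped") < 2) {
      warning(sprintf("set %s scored with fewer than 2 probe sets", nm),
              call. = FALSE)
    }
    as.numeric(sc)
  }), row.names = bx)
  names(out) <- c(pbt_cols, sup_cols)
  probs <- as.matrix(classifier_probs)[bx, prob_cols, drop = FALSE]
  if (anyNA(probs)) stop("classifier probabilities missing for some biopsies", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("classifier probabilities outside [0,1]", call. = FALSE)
  out[prob_cols] <- probs
  out <- out[c(pbt_cols, prob_cols, sup_cols)]
  structure(out, input_cols = c(pbt_cols, prob_cols),
            supplementary_cols = sup_cols,
            class = c("score_table", "data.frame"))
}

#' Column roles of a score table
#' @param table A `score_table`.
#' @return Character vector of the 10 model-input column names.
#' @export
input_columns <- function(table) attr(table, "input_cols")

#' @rdname input_columns
#' @export
supplementary_columns <- function(table) attr(table, "supplementary_cols")

#' Standardize score columns (z-score with stored parameters)
#'
#' Scores are standardized before PCA/AA. Each numeric score column is
#' centered and scaled (sd with the n-1 denominator); the training mean and
#' sd are stored so new samples can be projected with
#' [apply_standardization()].
#'
#' @param table A `score_table` (or plain data.frame of numeric columns).
#' @return The standardized table with attribute `standardization` (list of
#'   `mean` and `sd` per column).
#' @export
standardize <- function(table) {
  if (nrow(table) < 2) stop("need at least 2 biopsies to standardize", call. = FALSE)
  mu <- vapply(table, mean, numeric(1))
  sd_ <- vapply(table, stats::sd, numeric(1))
  zero <- names(sd_)[sd_ == 0]
  if (length(zero)) {
    stop("zero-variance column(s): ", paste(zero, collapse = ", "), call. = FALSE)
  }
  out <- apply_standardization(table, list(mean = mu, sd = sd_))
  out
}

#' @rdname standardize
#' @param params Stored standardization parameters (`mean`, `sd` per column).
#' @export
apply_standardization <- function(table, params) {
  out <- table
  for (nm in names(out)) {
    out[[nm]] <- (out[[nm]] - params$mean[[nm]]) / params$sd[[nm]]
  }
  attr(out, "standardization") <- params
  out
}

#' Pairwise Spearman correlations between score columns
#'
#' @param table Score table (or data.frame).
#' @param columns Columns to correlate; default the supplementary gene-set
#'   means if tagged, else all columns.
#' @return Symmetric matrix of Spearman rho with unit diagonal.
#' @export
pairwise_set_correlations <- function(table, columns = NULL) {
  if (is.null(columns)) {
    columns <- supplementary_columns(table)
    if (is.null(columns)) columns <- names(table)
  }
  if (nrow(table) < 3) stop("need at least 3 biopsies", call. = FALSE)
  stats::cor(as.matrix(table[columns]), method = "spearman")
}

#' Write / read a score table with its standardization sidecar
#'
#' CSV body plus a JSON sidecar (`<path>.json`) holding column roles and,
#' when present, standardization parameters.
#' @param table A `score_table`.
#' @param path CSV path.
#' @return `path` / the restored table.
#' @export
write_score_table <- function(table, path) {
  utils::write.csv(data.frame(sample_id = rownames(table), table,
                              check.names = FALSE),
                   path, row.names = FALSE)
  std <- attr(table, "standardization")
  if (!is.null(std)) std <- list(mean = as.list(std$mean), sd = as.list(std$sd))
  side <- list(input_cols = input_columns(table),
               supplementary_cols = supplementary_columns(table),
               standardization = std)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  std <- side$standardization
  if (!is.null(std)) std <- list(mean = unlist(std$mean), sd = unlist(std$sd))
  structure(df, input_cols = side$input_cols,
            supplementary_cols = side$supplementary_cols,
            standardization = std,
            class = c("score_table", "data.frame"))
}
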