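#' Build the biopsy-anchored death-censored survival frame
#'
#' One random biopsy per kidney (see [one_biopsy_per_kidney()]), time zero
#' at the biopsy, administrative censoring at 3 years, death with a
#' functioning graft treated as non-informative censoring. Predictor
#' columns from `scores` are joined by sample id.
#'
#' @param meta `sample_metadata` with follow-up fields.
#' @param scores Optional data.frame of per-biopsy predictors (rownames =
#'   sample ids), e.g. PC scores, archetype scores, gene-set means.
#' @param seed Seed for the per-kidney biopsy draw.
#' @param horizon_days Administrative censoring horizon (default 1095 = 3y).
#' @return A `survival_frame` data.frame: `kidney_id`, `sample_id`, `time`
#'   (days, > 0), `event` (0/1 graft failure), `txbx_days`, plus predictor
#'   columns; counts in `attr(,"counts")`.
#' @export
build_survival_frame <- function(meta, scores = NULL, seed = 1,
                                 horizon_days = 1095) {
  sel <- one_biopsy_per_kidney(meta, seed)
  zero <- !is.na(sel$followup_days) & sel$followup_days <= 0
  if (any(zero)) {
    message(sum(zero), " kidneys with zero follow-up beyond biopsy excluded")
    sel <- sel[!zero, , drop = FALSE]
  }
  if (!nrow(sel)) stop("no eligible kidneys", call. = FALSE)
  time <- pmin(sel$followup_days, horizon_days)
  event <- as.integer(sel$graft_failed == 1 &
                        sel$died_with_function == 0 &
                        sel$followup_days <= horizon_days)
  out <- data.frame(kidney_id = sel$kidney_id, sample_id = sel$sample_id,
                    time = time, event = event, txbx_days = sel$txbx_days,
                    stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    idx <- match(out$sample_id, rownames(scores))
    out <- cbind(out, as.data.frame(scores)[idx, , drop = FALSE])
    rownames(out) <- out$sample_id
  }
  attr(out, "counts") <- list(n_kidneys = nrow(out), n_events = sum(event),
                              n_censored = sum(event == 0),
                              dropped_kidneys = attr(sel, "dropped_kidneys"))
  class(out) <- c("survival_frame", "data.frame")
  out
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator of death-censored graft survival for each group
#' (typically the five injury archetype groups). Empty groups are dropped.
#'
#' @param frame A `survival_frame`.
#' @param groups Character/factor vector of group labels aligned with the
#'   frame rows (or a column name in the frame).
#' @return List: `fit` (the survfit object), `table` (tidy data.frame of
#'   group, time, n.risk, n.event, surv), `survival_at` function
#'   (`group`, `t`) -> survival probability.
#' @export
km_curve <- function(frame, groups = NULL) {
  if (is.character(groups) && length(groups) == 1 && groups %in% names(frame)) {
    groups <- frame[[groups]]
  }
  df <- data.frame(time = frame$time, event = frame$event)
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    grp_of <- function(strata) "all"
  } else {
    df$group <- if (is.factor(groups)) groups else factor(groups)
    empty <- setdiff(levels(df$group), unique(as.character(df$group)))
    if (length(empty)) {
      warning("empty group(s) dropped: ", paste(empty, collapse = ", "), call. = FALSE)
      df$group <- droplevels(df$group)
    }
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  }
  s <- summary(fit, censored = TRUE)
  tab <- data.frame(
    group = if (is.null(groups)) "all" else sub("^group=", "", as.character(s$strata)),
    time = s$time, n.risk = s$n.risk, n.event = s$n.event, surv = s$surv,
    stringsAsFactors = FALSE
  )
  survival_at <- function(group, t) {
    g <- tab[tab$group == group, , drop = FALSE]
    g <- g[g$time <= t, , drop = FALSE]
    if (!nrow(g)) 1 else g$surv[nrow(g)]
  }
  list(fit = fit, table = tab, survival_at = survival_at)
}

#' Cox model with time-varying injury-component effects
#'
#' Proportional-hazards fit with a main effect per component and an
#' interaction with a transform of time posttransplant at biopsy
#' (`g = log(days)` by default), so the log-hazard effect of component j is
#' `beta_j(t) = main_j + interaction_j * g(t)`. TxBx is a baseline
#' covariate here (biopsy timing), not follow-up time. Pointwise confidence
#' bands come from the coefficient covariance (delta method).
#'
#' @param frame A `survival_frame` containing the component columns.
#' @param pcs Component column names (default `c("PC1", "PC3")`).
#' @param time_transform `"log"` (natural log of TxBx days) or `"linear"`.
#' @param center_days Reference TxBx at which the main effect is reported
#'   (g is centered there; default 365).
#' @return A `cox_time_interaction` list: `fit`, `coef`, `vcov`, and
#'   `effects` -- per component a function `beta(t)` plus a data.frame of
#'   `t`, `beta`, `lower`, `upper` over the observed TxBx range.
#' @export
cox_time_interaction <- function(frame, pcs = c("PC1", "PC3"),
                                 time_transform = c("log", "linear"),
                                 center_days = 365) {
  time_transform <- match.arg(time_transform)
  g <- if (time_transform == "log") {
    function(t) log(t) - log(center_days)
  } else {
    function(t) (t - center_days) / 365
  }
  miss <- setdiff(pcs, names(frame))
  if (length(miss)) stop("missing component column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(frame)[c("time", "event", "txbx_days", pcs)]
  for (p in pcs) {
    if (stats::sd(df[[p]]) == 0) stop("degenerate predictor: ", p, call. = FALSE)
  }
  df$g_txbx <- g(df$txbx_days)
  n_par <- 1 + 2 * length(pcs)
  if (sum(df$event) < 10 * n_par) {
    warning(sprintf("only %d events for %d parameters", sum(df$event), n_par),
            call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ g_txbx +",
    paste(pcs, collapse = " + "), "+",
    paste(paste0(pcs, ":g_txbx"), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df)
  if (!fit$iter || any(!is.finite(stats::coef(fit)))) {
    stop("Cox model failed to converge; coefficients: ",
         paste(round(stats::coef(fit), 3), collapse = ", "), call. = FALSE)
  }
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  t_grid <- exp(seq(log(max(min(df$txbx_days), 1)), log(max(df$txbx_days)),
                    length.out = 100))
  effects <- lapply(setNames(pcs, pcs), function(p) {
    main <- cf[[p]]
    inter_name <- if (paste0(p, ":g_txbx") %in% names(cf)) paste0(p, ":g_txbx")
                  else paste0("g_txbx:", p)
    inter <- cf[[inter_name]]
    beta <- function(t) main + inter * g(t)
    gv <- g(t_grid)
    se <- sqrt(V[p, p] + gv^2 * V[inter_name, inter_name] +
                 2 * gv * V[p, inter_name])
    curve <- data.frame(t = t_grid, beta = main + inter * gv,
                        lower = main + inter * gv - 1.96 * se,
                        upper = main + inter * gv + 1.96 * se)
    list(main = main, interaction = inter, beta = beta, curve = curve)
  })
  structure(list(fit = fit, coef = cf, vcov = V, effects = effects,
                 time_transform = time_transform, center_days = center_days),
            class = "cox_time_interaction")
}

#' Random survival forest variable importance
#'
#' Survival forest on the frame's predictors with permutation importance
#' and out-of-bag error defined as 1 minus Harrell's C. Splits are random
#' (one candidate split value per variable), mirroring the model's
#' reference configuration; `ntree` is a runtime choice and is
#' configurable. Missing predictor values are median-imputed. Predictor
#' columns are sorted internally so the result does not depend on column
#' order.
#'
#' @param frame A `survival_frame`.
#' @param predictors Predictor column names.
#' @param ntree Number of trees (default 5000).
#' @param nsplit Random candidate splits per variable (default 1).
#' @param seed Integer seed.
#' @return List: `importance` (named, sorted decreasing), `oob_error`
#'   (1 - C), `fit` (the ranger object).
#' @export
rsf_importance <- function(frame, predictors, ntree = 5000, nsplit = 1,
                           seed = 1) {
  predictors <- sort(predictors)
  miss <- setdiff(predictors, names(frame))
  if (length(miss)) stop("missing predictor(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- as.data.frame(frame)[c("time", "event", predictors)]
  for (p in predictors) {
    v <- df[[p]]
    if (anyNA(v)) df[[p]] <- ifelse(is.na(v), stats::median(v, na.rm = TRUE), v)
    if (stats::sd(df[[p]]) == 0) {
      warning("constant predictor: ", p, " (importance will be zero)", call. = FALSE)
    }
  }
  fit <- ranger::ranger(
    survival::Surv(time, event) ~ ., data = df,
    num.trees = ntree, splitrule = "extratrees", num.random.splits = nsplit,
    importance = "permutation", seed = seed, num.threads = 1
  )
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  list(importance = imp, oob_error = fit$prediction.error, fit = fit)
}

#' Harrell's concordance statistic
#'
#' Probability over usable pairs that the subject with higher predicted
#' risk fails first; tied risks count one half.
#'
#' @param risk Numeric risk scores (higher = earlier failure expected).
#' @param frame A `survival_frame` (or anything with `time` and `event`).
#' @return C in \[0,1\].
#' @export
c_statistic <- function(risk, frame) {
  time <- frame$time; event <- frame$event
  cc <- survival::concordance(survival::Surv(time, event) ~ risk, reverse = TRUE)
  n_pairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) stop("no comparable pairs", call. = FALSE)
  unname(cc$concordance)
}

# ---- restricted cubic splines -------------------------------------------

# Harrell's restricted cubic basis: linear tails, k-2 nonlinear terms,
# knots t; scaled by (t_k - t_1)^2
rcs_basis <- function(x, knots) {
  k <- length(knots)
  t1 <- knots[1]; tk <- knots[k]; tk1 <- knots[k - 1]
  pos3 <- function(u) pmax(u, 0)^3
  nl <- vapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (pos3(x - tj) - pos3(x - tk1) * (tk - tj) / (tk - tk1) +
       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
  }, numeric(length(x)))
  cbind(x = x, nl)
}

#' Fit a restricted cubic spline curve
#'
#' Three knots at the 0.10/0.50/0.90 quantiles of `x` (Harrell's
#' convention), restricted cubic basis with linear tails, least-squares
#' coefficients. Used for the score-versus-log(TxBx) and score-versus-eGFR
#' curves.
#'
#' @param y Response.
#' @param x Predictor.
#' @param n_knots Number of knots (default 3; knot quantiles equally spaced
#'   between 0.10 and 0.90 for other counts).
#' @return An `rcs_fit` list: `knots`, `coef`, and use [rcs_predict()] to
#'   evaluate.
#' @export
rcs_fit <- function(y, x, n_knots = 3) {
  if (length(x) < 10) stop("need at least 10 observations", call. = FALSE)
  qs <- seq(0.10, 0.90, length.out = n_knots)
  knots <- unname(stats::quantile(x, qs, type = 7))
  if (length(unique(knots)) < n_knots || length(unique(x)) < n_knots) {
    stop("insufficient distinct x values for the knots", call. = FALSE)
  }
  B <- rcs_basis(x, knots)
  fit <- stats::lm.fit(cbind(1, B), y)
  structure(list(knots = knots, coef = fit$coefficients,
                 fitted = fit$fitted.values),
            class = "rcs_fit")
}

#' @rdname rcs_fit
#' @param fit An `rcs_fit`.
#' @param newx Points at which to evaluate the curve.
#' @export
rcs_predict <- function(fit, newx) {
  B <- rcs_basis(newx, fit$knots)
  as.numeric(cbind(1, B) %*% fit$coef)
}

#' Spearman correlation of each score with a covariate
#'
#' Tie-corrected Spearman rho and p-value per score column; used for donor
#' age, eGFR and single-gene (e.g. MKI67 probe) associations.
#'
#' @param scores Data frame or matrix of per-biopsy scores.
#' @param covariate Numeric vector aligned with the score rows.
#' @return Data frame: `score`, `rho`, `p`.
#' @export
correlate_with_covariate <- function(scores, covariate) {
  s <- as.data.frame(scores)
  if (nrow(s) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(covariate) == 0) stop("constant covariate", call. = FALSE)
  res <- lapply(names(s), function(nm) {
    ct <- suppressWarnings(stats::cor.test(s[[nm]], covariate,
                                           method = "spearman", exact = FALSE))
    data.frame(score = nm, rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

#' Per-group clinical and molecular summaries
#'
#' For each archetype group: n, median TxBx, mean eGFR, mean donor age,
#' percent donors aged >= 50, and the mean of any provided score columns.
#' Epoch-stratified variants use early = TxBx <= 42 days, late = TxBx > 365
#' days.
#'
#' @param meta `sample_metadata` rows aligned with `groups`.
#' @param groups Group label per biopsy.
#' @param scores Optional data.frame of score columns (same order).
#' @param epoch One of "all", "early", "late".
#' @return Data frame, one row per group (empty groups keep n = 0 with
#'   missing statistics).
#' @export
group_summaries <- function(meta, groups, scores = NULL,
                            epoch = c("all", "early", "late")) {
  epoch <- match.arg(epoch)
  keep <- switch(epoch,
                 all = rep(TRUE, nrow(meta)),
                 early = meta$txbx_days <= 42,
                 late = meta$txbx_days > 365)
  if (!is.factor(groups)) groups <- factor(groups)
  out <- lapply(levels(groups), function(g) {
    i <- which(keep & groups == g)
    row <- data.frame(
      group = g, n = length(i),
      median_txbx = if (length(i)) stats::median(meta$txbx_days[i]) else NA_real_,
      mean_egfr = if (length(i)) mean(meta$egfr[i], na.rm = TRUE) else NA_real_,
      mean_donor_age = if (length(i)) mean(meta$donor_age[i], na.rm = TRUE) else NA_real_,
      pct_donor_age_ge50 = if (length(i)) 100 * mean(meta$donor_age[i] >= 50, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(scores)) {
      sm <- if (length(i)) colMeans(as.data.frame(scores)[i, , drop = FALSE])
            else setNames(rep(NA_real_, ncol(scores)), colnames(scores))
      row <- cbind(row, as.data.frame(as.list(sm)))
    }
    row
  })
  do.call(rbind, out)
}
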