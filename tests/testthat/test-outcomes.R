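test_that("survival frame applies the 3-year death-censored rules", {
  meta <- toy_metadata(3)
  meta$kidney_id <- paste0("K", 1:3)
  meta$followup_days <- c(400, 200, 1200)
  meta$graft_failed <- c(1, 0, 1)
  meta$died_with_function <- c(0, 1, 0)
  fr <- build_survival_frame(meta, seed = 1)
  fr <- fr[order(fr$sample_id), ]
  expect_equal(fr$time, c(400, 200, 1095))
  expect_equal(fr$event, c(1L, 0L, 0L))   # death-censored; administrative at 3y
  expect_equal(nrow(fr), length(unique(meta$kidney_id)))
})

test_that("survival frame conserves kidneys and joins predictors by sample id", {
  co <- small_cohort()
  scores <- data.frame(PC1 = rnorm(nrow(co$meta)),
                       row.names = co$meta$sample_id)
  fr <- build_survival_frame(co$meta, scores, seed = 3)
  eligible <- unique(co$meta$kidney_id[!is.na(co$meta$followup_days) &
                                         co$meta$followup_days > 0])
  expect_equal(sort(fr$kidney_id), sort(eligible))
  expect_equal(fr$PC1, scores[fr$sample_id, "PC1"])
  expect_true(all(fr$time > 0))
  meta_none <- co$meta; meta_none$followup_days <- NA
  expect_error(build_survival_frame(meta_none, seed = 1), "no eligible")
})

test_that("Kaplan-Meier estimates equal the hand product-limit computation", {
  fr <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_curve(fr)
  expect_equal(km$survival_at("all", 1), 2 / 3)
  expect_equal(km$survival_at("all", 2), 2 / 3)
  expect_equal(km$survival_at("all", 3), 0)
  # no events -> survival 1 everywhere
  km0 <- km_curve(data.frame(time = c(5, 6), event = c(0, 0)))
  expect_equal(km0$survival_at("all", 100), 1)
  # random toys against the brute-force estimator
  set.seed(16)
  for (i in 1:5) {
    d <- data.frame(time = sample(1:10, 12, TRUE), event = rbinom(12, 1, 0.6))
    km_i <- km_curve(d)
    for (t in c(2, 5, 9)) {
      expect_equal(km_i$survival_at("all", t), km_brute(d$time, d$event, t),
                   tolerance = 1e-12)
    }
  }
})

test_that("per-group KM drops empty groups with a warning", {
  fr <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  g <- factor(c("a", "a", "b", "b"), levels = c("a", "b", "c"))
  expect_warning(km <- km_curve(fr, g), "empty group")
  expect_setequal(unique(km$table$group), c("a", "b"))
})

test_that("Harrell's C matches brute-force pair enumeration", {
  # risk equal to reversed event-time order -> C = 1
  fr <- data.frame(time = c(1, 2, 3, 4, 5), event = rep(1, 5))
  expect_equal(c_statistic(c(5, 4, 3, 2, 1), fr), 1.0)
  expect_equal(c_statistic(rep(2, 5), fr), 0.5)
  set.seed(17)
  for (i in 1:5) {
    fr <- data.frame(time = sample(1:8, 5, TRUE), event = rbinom(5, 1, 0.7))
    if (sum(fr$event) == 0) next
    risk <- rnorm(5)
    expect_equal(c_statistic(risk, fr), c_brute(risk, fr$time, fr$event),
                 tolerance = 1e-12)
  }
})

test_that("restricted cubic splines reproduce affine functions and have linear tails", {
  set.seed(18)
  x <- runif(50, 0, 10)
  y <- 2 + 3 * x
  fit <- rcs_fit(y, x)
  expect_equal(rcs_predict(fit, x), y, tolerance = 1e-8)
  expect_equal(length(fit$knots), 3)
  expect_equal(fit$knots, unname(quantile(x, c(0.1, 0.5, 0.9))))
  # second difference beyond the boundary knots is zero (linear tails)
  far <- max(x) + c(1, 2, 3)
  pred <- rcs_predict(fit, far)
  expect_equal(diff(pred, differences = 2), 0, tolerance = 1e-8)
  low <- min(x) - c(3, 2, 1)
  expect_equal(diff(rcs_predict(fit, low), differences = 2), 0, tolerance = 1e-8)
  expect_error(rcs_fit(y[1:5], x[1:5]), "at least 10")
  expect_error(rcs_fit(rep(1, 20), rep(c(1, 2), 10)), "distinct")
})

test_that("restricted cubic splines recover a known curve from noisy data", {
  set.seed(19)
  x <- runif(1000, 0, 10)
  knots <- c(1, 5, 9)
  truth_fit <- structure(list(knots = knots, coef = c(0.5, 0.8, -2.0)),
                         class = "rcs_fit")
  truth <- rcs_predict(truth_fit, x)
  y <- truth + rnorm(1000, 0, 0.1)
  fit <- rcs_fit(y, x)
  rmse <- sqrt(mean((rcs_predict(fit, x) - truth)^2))
  expect_lt(rmse, 0.05)
})

test_that("Cox fit with time interaction recovers a planted constant effect", {
  set.seed(20)
  n <- 2000
  z <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("PC1", "PC3")))
  txbx <- exp(runif(n, log(3), log(5475)))
  lp <- 0.5 * z[, "PC3"]   # constant effect, no interaction
  surv <- simulate_survival(lp, h0 = 5e-4, death_rate = 0, seed = 20)
  fr <- data.frame(time = pmin(surv$followup_days, 1095),
                   event = as.integer(surv$graft_failed == 1 & surv$followup_days <= 1095),
                   txbx_days = txbx, z)
  fit <- cox_time_interaction(fr, pcs = c("PC1", "PC3"))
  expect_lt(abs(fit$effects$PC3$main - 0.5), 0.15)
  expect_lt(abs(fit$effects$PC3$interaction), 0.1)
  expect_lt(abs(fit$effects$PC1$main), 0.15)
  # beta(t) reproducible from stored coefficients
  expect_equal(fit$effects$PC3$beta(365), fit$effects$PC3$main, tolerance = 1e-12)
  expect_error(cox_time_interaction(fr, pcs = "nope"), "missing component")
  fr$PC1 <- 0
  expect_error(cox_time_interaction(fr, pcs = "PC1"), "degenerate")
})

test_that("random survival forest ranks predictors independent of column order", {
  set.seed(21)
  n <- 400
  x <- data.frame(sig = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  surv <- simulate_survival(1.0 * x$sig, h0 = 5e-4, death_rate = 0, seed = 21)
  fr <- data.frame(time = surv$followup_days, event = surv$graft_failed, x)
  r1 <- rsf_importance(fr, c("sig", "n1", "n2"), ntree = 300, seed = 2)
  r2 <- rsf_importance(fr, c("n2", "n1", "sig"), ntree = 300, seed = 2)
  expect_identical(r1$importance, r2$importance)
  expect_equal(names(r1$importance)[1], "sig")
  expect_lt(r1$oob_error, 0.5)
  fr$k <- 1
  expect_warning(r3 <- rsf_importance(fr, c("sig", "k"), ntree = 100, seed = 1),
                 "constant predictor")
})

test_that("importance of a duplicated predictor is shared but stays above noise", {
  set.seed(22)
  n <- 500
  sig <- rnorm(n)
  surv <- simulate_survival(1.2 * sig, h0 = 5e-4, death_rate = 0, seed = 22)
  fr <- data.frame(time = surv$followup_days, event = surv$graft_failed,
                   dup1 = sig, dup2 = sig, n1 = rnorm(n), n2 = rnorm(n),
                   n3 = rnorm(n))
  r <- rsf_importance(fr, c("dup1", "dup2", "n1", "n2", "n3"), ntree = 500, seed = 3)
  noise_max <- max(r$importance[c("n1", "n2", "n3")])
  expect_gt(r$importance["dup1"], noise_max)
  expect_gt(r$importance["dup2"], noise_max)
})

test_that("Spearman associations match brute force and respect preconditions", {
  set.seed(23)
  s <- data.frame(a = rnorm(5), b = rnorm(5))
  cov <- rnorm(5)
  res <- correlate_with_covariate(s, cov)
  expect_equal(res$rho[1], spearman_brute(s$a, cov), tolerance = 1e-12)
  # monotone transform of a score -> rho 1
  res2 <- correlate_with_covariate(data.frame(a = s$a), exp(s$a))
  expect_equal(res2$rho, 1)
  expect_error(correlate_with_covariate(s, rep(1, 5)), "constant")
  expect_error(correlate_with_covariate(s[1:2, ], cov[1:2]), "at least 3")
})

test_that("group summaries reduce to cohort statistics and count older donors", {
  meta <- toy_metadata(10)
  g1 <- rep("all", 10)
  s <- group_summaries(meta, g1)
  expect_equal(s$n, 10)
  expect_equal(s$median_txbx, median(meta$txbx_days))
  expect_equal(s$mean_egfr, mean(meta$egfr))
  meta2 <- toy_metadata(2)
  meta2$donor_age <- c(40, 60)
  expect_equal(group_summaries(meta2, c("g", "g"))$pct_donor_age_ge50, 50)
  # empty group keeps a row with n = 0
  g3 <- factor(rep("a", 10), levels = c("a", "b"))
  s3 <- group_summaries(meta, g3)
  expect_equal(s3$n[s3$group == "b"], 0)
  expect_true(is.na(s3$mean_egfr[s3$group == "b"]))
  # epoch stratification
  meta$txbx_days <- c(rep(10, 4), rep(1000, 6))
  expect_equal(group_summaries(meta, g1, epoch = "early")$n, 4)
  expect_equal(group_summaries(meta, g1, epoch = "late")$n, 6)
})
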