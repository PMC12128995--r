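# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small cohort for cheap module tests (compact array)
small_cohort <- function() {
  cached("small", function() {
    generate_cohort(cohort_config(n_biopsies = 500, n_probesets = 400, seed = 42))
  })
}

# the reference end-to-end cohort + fitted model (shared by the recovery and
# projection tests); sized to the study conditions
reference_model <- function() {
  cached("reference", function() {
    co <- generate_cohort(cohort_config(seed = 101))
    fit <- run_injury_pipeline(co$expr, co$meta, co$sets, seed = 101)
    tr <- co$truth[match(rownames(fit$pca$scores), co$truth$sample_id), ]
    meta <- fit$meta[match(rownames(fit$pca$scores), fit$meta$sample_id), ]
    list(cohort = co, fit = fit, truth = tr, meta = meta)
  })
}

# tiny hand-checkable expression matrix: 3 probes, 2 controls, 2 biopsies
toy_expression <- function() {
  vals <- rbind(
    p1 = c(S1 = 4, S2 = 3, C1 = 3, C2 = 3),
    p2 = c(S1 = 7, S2 = 5, C1 = 5, C2 = 5),
    p3 = c(S1 = 1, S2 = 2, C1 = 2, C2 = 2)
  )
  expression_matrix(vals, control_ids = c("C1", "C2"))
}

toy_metadata <- function(n = 6, seed = 1) {
  set.seed(seed)
  validate_metadata(data.frame(
    sample_id = paste0("S", seq_len(n)),
    kidney_id = paste0("K", rep_len(seq_len(ceiling(n / 2)), n)),
    txbx_days = exp(runif(n, log(3), log(5000))),
    egfr = runif(n, 15, 90), donor_age = runif(n, 20, 70),
    proteinuria_pos = rbinom(n, 1, 0.3), ci_score = sample(0:3, n, TRUE),
    ct_score = sample(0:3, n, TRUE), pct_cortex = runif(n, 20, 90),
    followup_days = runif(n, 100, 3000), graft_failed = rbinom(n, 1, 0.3),
    died_with_function = 0, stringsAsFactors = FALSE
  ))
}

# brute-force Spearman rho via the rank formula
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force product-limit estimator at the observed event times
km_brute <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# brute-force Harrell's C over all usable pairs
c_brute <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # usable: the smaller time is an event
    if (time[i] == time[j] && event[i] == 1 && event[j] == 1) next
    first <- if (time[i] < time[j]) i else if (time[j] < time[i]) j else NA
    if (is.na(first)) {
      # equal times, one event: event subject should have higher risk
      ev <- if (event[i] == 1) i else if (event[j] == 1) j else NA
      if (is.na(ev)) next
      other <- setdiff(c(i, j), ev)
      den <- den + 1
      num <- num + if (risk[ev] > risk[other]) 1 else if (risk[ev] == risk[other]) 0.5 else 0
      next
    }
    if (event[first] != 1) next
    other <- setdiff(c(i, j), first)
    den <- den + 1
    num <- num + if (risk[first] > risk[other]) 1 else if (risk[first] == risk[other]) 0.5 else 0
  }
  num / den
}

# match archetypes to reference vertices greedily by distance, return the
# per-archetype distances under the optimal (enumerated) assignment
match_vertices <- function(archetypes, vertices) {
  k <- nrow(vertices)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  for (p in perms(seq_len(k))) {
    d <- sqrt(rowSums((archetypes[p, , drop = FALSE] - vertices)^2))
    if (is.null(best) || sum(d) < sum(best)) best <- d
  }
  best
}
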