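#' Configuration for a synthetic transplant biopsy cohort
#'
#' The generator emulates a biopsy population whose expression variance is
#' driven by three latent injury axes: `z1` acute injury + inflammation,
#' `z2` chronicity coupled to time posttransplant (TxBx), and `z3`
#' epithelial remodeling. Five states are planted at fixed points in latent
#' space (normal at the origin; AKI1, AKI2, mild CKD, CKDAKI at vertices),
#' and every downstream quantity (donor age, eGFR, histology labels,
#' death-censored survival) is linked to the latents through the
#' coefficients stored here, so the whole pipeline can be checked against
#' ground truth.
#'
#' Defaults: biopsy times log-uniform over 3 days to 15 years; donor-age /
#' remodeling-axis coupling 0.2; acute-axis log-hazard increasing linearly
#' in log TxBx while the remodeling-axis effect is constant.
#'
#' @param n_biopsies Number of biopsies.
#' @param n_controls Number of control (nephrectomy) samples; default 4.
#' @param n_probesets Number of probe sets on the simulated array.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config (no hidden constants).
#' @param gene_set_sizes Named integer vector of probes per gene set; by
#'   default 30 for each of the six input PBTs and 15 for each of the twelve
#'   failed-repair sets.
#' @param latent_params List: `state_centers` (5 x 3 matrix), `within_sd`
#'   (per-axis sd around the state center), `time_coupling` (z2 loading on
#'   standardized log TxBx), `set_loadings` (set name -> length-3 loading on
#'   z1,z2,z3), `loading_jitter` (per-gene multiplier range), `baseline_mean`,
#'   `baseline_sd`, `noise_sd` (per-gene residual sd, log2 units).
#' @param time_model List: `min_days`, `max_days` for the log-uniform TxBx.
#' @param age_model List: `mean`, `sd`, `coupling` (Pearson coupling of donor
#'   age to standardized z3), `range` clamp.
#' @param egfr_model List: `base`, `slope_z1`, `slope_z2`, `slope_z3`,
#'   `noise_sd`, `floor`.
#' @param pheno_model List: logistic intercept/slopes for proteinuria, ci/ct
#'   latent noise sd and cutpoints, cortex range and low-cortex fraction,
#'   fraction of biopsies with follow-up recorded, biopsies-per-kidney rate.
#' @param hazard_params List: `h0` baseline daily hazard, `b1` acute-axis
#'   log-hazard at 1 year, `b1_time_slope` per unit log(TxBx days / 365),
#'   `b3` remodeling-axis log-hazard, `death_rate` daily hazard of death
#'   with function (independent), `admin_range` administrative censoring
#'   window (days).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_biopsies = 4000,
                          n_controls = 4,
                          n_probesets = 2000,
                          seed = 1,
                          gene_set_sizes = NULL,
                          latent_params = NULL,
                          time_model = list(min_days = 3, max_days = 5475),
                          age_model = list(mean = 45, sd = 13, coupling = 0.2,
                                           range = c(15, 80)),
                          egfr_model = list(base = 60, slope_z1 = -8,
                                            slope_z2 = 3, slope_z3 = -5,
                                            noise_sd = 8, floor = 5),
                          pheno_model = NULL,
                          hazard_params = NULL) {
  if (is.null(gene_set_sizes)) {
    gene_set_sizes <- c(
      setNames(rep(30L, 6), input_pbt_names()),
      setNames(rep(15L, 12), new_set_names())
    )
  }
  if (is.null(latent_params)) latent_params <- default_latent_params()
  if (is.null(pheno_model)) {
    pheno_model <- list(
      prot_intercept = -1.2, prot_z1 = 0.5, prot_z2 = 0.4,
      lesion_noise_sd = 0.7, ci_cuts = c(0, 1.2, 2.4), ct_cuts = c(0, 1.2, 2.4),
      cortex_range = c(30, 95), low_cortex_frac = 0.03,
      followup_frac = 0.8, biopsies_per_kidney = 1.25
    )
  }
  if (is.null(hazard_params)) {
    hazard_params <- list(h0 = 1.5e-4, b1 = 0.4, b1_time_slope = 0.25,
                          b3 = 0.35, death_rate = 6e-5,
                          admin_range = c(365, 3650), censoring_rate = NA_real_)
  }
  cfg <- list(n_biopsies = n_biopsies, n_controls = n_controls,
              n_probesets = n_probesets, seed = seed,
              gene_set_sizes = gene_set_sizes, latent_params = latent_params,
              time_model = time_model, age_model = age_model,
              egfr_model = egfr_model, pheno_model = pheno_model,
              hazard_params = hazard_params)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

input_pbt_names <- function() c("IRRAT30", "IRITD3", "IRITD5", "DAMP", "MCAT", "IGT")

classifier_prob_names <- function() c("lowGFR_Prob", "Prot_Prob", "ci_gt1_Prob", "ct_gt1_Prob")

#' Names of the twelve failed-repair gene sets
#'
#' Four biological states (New1 oxidative stress, New2 hypoxia, New3
#' interferon response, New4 EMT) per nephron segment (PT, TAL, DCT), with
#' the thin-limb set tL-New1 substituted for TAL-New1, which is too small to
#' score.
#' @return Character vector of 12 set names.
#' @export
new_set_names <- function() {
  segs <- c("PT", "TAL", "DCT")
  nm <- as.vector(outer(segs, paste0("New", 1:4), paste, sep = "_"))
  nm[nm == "TAL_New1"] <- "tL_New1"
  nm
}

state_names <- function() c("normal", "AKI1", "AKI2", "mildCKD", "CKDAKI")

default_latent_params <- function() {
  # five states at vertices in latent space; all injured states share a
  # large acute-axis (z1) displacement so a global injury factor dominates,
  # the chronic axis (z2) separates CKD from AKI states, and the remodeling
  # axis (z3) separates AKI1 from AKI2 and CKDAKI from mild CKD
  centers <- rbind(normal  = c(0.0,  0.0, 0.0),
                   AKI1    = c(1.6, -1.0, 2.4),
                   AKI2    = c(3.2, -1.0, 0.2),
                   mildCKD = c(1.8,  1.3, 0.2),
                   CKDAKI  = c(3.5,  1.3, 2.0))
  colnames(centers) <- c("z1", "z2", "z3")
  loadings <- list(
    IRRAT30 = c(1.00, -0.45,  0.00),
    IRITD3  = c(1.00, -0.45,  0.45),
    IRITD5  = c(1.00, -0.45,  0.45),
    DAMP    = c(1.00, -0.45, -0.45),
    MCAT    = c(0.70,  0.55, -0.45),
    IGT     = c(0.70,  0.55,  0.00)
  )
  for (seg in c("PT", "TAL", "DCT")) {
    n1 <- if (seg == "TAL") "tL_New1" else paste0(seg, "_New1")
    loadings[[n1]] <- c(-0.40, 0.00, 0.30)
    loadings[[paste0(seg, "_New2")]] <- c(0.50, -0.20, 0.30)
    loadings[[paste0(seg, "_New3")]] <- c(0.50, -0.20, 0.30)
    loadings[[paste0(seg, "_New4")]] <- c(0.70, -0.20, 0.50)
  }
  list(state_centers = centers, within_sd = 0.45, time_coupling = 0.6,
       set_loadings = loadings, loading_jitter = c(0.7, 1.3),
       baseline_mean = 8, baseline_sd = 1.2, noise_sd = 0.4,
       state_probs_early = c(normal = 0.30, AKI1 = 0.20, AKI2 = 0.30,
                             mildCKD = 0.10, CKDAKI = 0.10),
       state_probs_late = c(normal = 0.30, AKI1 = 0.05, AKI2 = 0.05,
                            mildCKD = 0.30, CKDAKI = 0.30))
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  counts <- c(cfg$n_biopsies, cfg$n_controls, cfg$n_probesets)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("n_biopsies, n_controls, n_probesets must be positive integers",
         call. = FALSE)
  }
  if (cfg$latent_params$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$latent_params$within_sd < 0) stop("within_sd must be >= 0", call. = FALSE)
  need <- sum(cfg$gene_set_sizes) + 1L  # +1 for the MKI67-like probe
  if (cfg$n_probesets < need) {
    stop(sprintf("n_probesets (%d) smaller than total gene-set size (%d)",
                 cfg$n_probesets, need), call. = FALSE)
  }
  if (!setequal(names(cfg$latent_params$set_loadings), names(cfg$gene_set_sizes))) {
    stop("set_loadings and gene_set_sizes must name the same sets", call. = FALSE)
  }
  cr <- suppressWarnings(as.numeric(cfg$hazard_params$censoring_rate))
  if (length(cr) == 1 && is.finite(cr) && (cr < 0 || cr > 1)) {
    stop("censoring_rate must be in [0,1]", call. = FALSE)
  }
  cfg
}

#' Serialize / deserialize a cohort config
#'
#' JSON round trip is lossless: reading back a written config reproduces the
#' generator output byte for byte.
#' @param cfg A `cohort_config`.
#' @param path File path.
#' @return `read_cohort_config` returns the config; `write_cohort_config`
#'   returns `path` invisibly.
#' @export
write_cohort_config <- function(cfg, path) {
  validate_cohort_config(cfg)
  out <- unclass(cfg)
  # jsonlite drops names on atomic vectors; named members go out as objects
  out$gene_set_sizes <- as.list(out$gene_set_sizes)
  out$latent_params$state_probs_early <- as.list(out$latent_params$state_probs_early)
  out$latent_params$state_probs_late <- as.list(out$latent_params$state_probs_late)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$gene_set_sizes <- unlist(raw$gene_set_sizes)
  lp <- raw$latent_params
  lp$state_centers <- structure(as.matrix(lp$state_centers),
                                dimnames = list(state_names(), c("z1", "z2", "z3")))
  lp$set_loadings <- lapply(lp$set_loadings, unlist)
  lp$state_probs_early <- unlist(lp$state_probs_early)
  lp$state_probs_late <- unlist(lp$state_probs_late)
  raw$latent_params <- lp
  raw$hazard_params$censoring_rate <-
    if (is.null(raw$hazard_params$censoring_rate)) NA_real_ else raw$hazard_params$censoring_rate
  class(raw) <- "cohort_config"
  validate_cohort_config(raw)
}

# probe layout: contiguous blocks per set, then the MKI67-like probe, then
# unassigned noise probes; deterministic in the config alone
probe_layout <- function(cfg) {
  sizes <- cfg$gene_set_sizes
  ids <- sprintf("PS%05d", seq_len(cfg$n_probesets))
  sets <- vector("list", length(sizes))
  names(sets) <- names(sizes)
  at <- 1L
  for (nm in names(sizes)) {
    sets[[nm]] <- ids[at:(at + sizes[[nm]] - 1L)]
    at <- at + sizes[[nm]]
  }
  list(ids = ids, sets = sets, mki67 = ids[at])
}

# per-gene loading matrix (p x 3) implied by the config
loading_matrix <- function(cfg, layout, jitter) {
  p <- cfg$n_probesets
  L <- matrix(0, p, 3, dimnames = list(layout$ids, c("z1", "z2", "z3")))
  for (nm in names(layout$sets)) {
    rows <- layout$sets[[nm]]
    base <- cfg$latent_params$set_loadings[[nm]]
    L[rows, ] <- outer(jitter[rows], base)
  }
  L[layout$mki67, ] <- c(0.5, -0.4, 0.1)  # mitosis-like single gene
  L
}

#' Generate a synthetic biopsy cohort
#'
#' Draws biopsy times, planted states, latent axis values, expression
#' (per-gene baseline + loadings x latents + Gaussian noise, log2 scale),
#' clinical metadata (donor age coupled to the remodeling axis, eGFR
#' decreasing in z1 and z3, proteinuria and ci/ct through logistic/ordinal
#' links on the latents), and death-censored follow-up from a hazard whose
#' acute-axis coefficient grows linearly in log TxBx.
#'
#' @param config A [cohort_config()].
#' @return List with `expr` (an [expression_matrix()] holding biopsies and
#'   controls), `meta` (`sample_metadata`), `sets` (gene-set collection:
#'   the 6 input PBTs plus the 12 failed-repair sets), and `truth`
#'   (per-biopsy latent scores, planted state, hazard multiplier).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  lp <- cfg$latent_params
  n <- cfg$n_biopsies
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))

  layout <- probe_layout(cfg)
  baseline <- stats::rnorm(cfg$n_probesets, lp$baseline_mean, lp$baseline_sd)
  names(baseline) <- layout$ids
  jitter <- stats::runif(cfg$n_probesets, lp$loading_jitter[1], lp$loading_jitter[2])
  names(jitter) <- layout$ids
  L <- loading_matrix(cfg, layout, jitter)

  # biopsy times, log-uniform
  lt_range <- log(c(cfg$time_model$min_days, cfg$time_model$max_days))
  logt <- stats::runif(n, lt_range[1], lt_range[2])
  txbx <- exp(logt)
  slog <- (logt - mean(lt_range)) / (diff(lt_range) / sqrt(12))

  # planted states, mixing early-dominant and late-dominant compositions
  w <- (logt - lt_range[1]) / diff(lt_range)
  pmat <- outer(1 - w, lp$state_probs_early) + outer(w, lp$state_probs_late)
  state <- apply(pmat, 1L, function(p) sample(state_names(), 1L, prob = p))

  # latents: state center + within-state noise; z2 additionally coupled to
  # standardized log TxBx
  centers <- lp$state_centers[state, , drop = FALSE]
  z <- centers + matrix(stats::rnorm(3 * n, 0, lp$within_sd), n, 3)
  z[, 2] <- z[, 2] + lp$time_coupling * slog
  colnames(z) <- c("z1", "z2", "z3")

  # expression: baseline + L z' + noise; controls at latent origin
  bx_ids <- sprintf("BX%05d", seq_len(n))
  ctl_ids <- sprintf("CTL%d", seq_len(cfg$n_controls))
  noise <- matrix(stats::rnorm(cfg$n_probesets * (n + cfg$n_controls),
                               0, lp$noise_sd),
                  cfg$n_probesets, n + cfg$n_controls)
  vals <- baseline + cbind(L %*% t(z), matrix(0, cfg$n_probesets, cfg$n_controls)) + noise
  dimnames(vals) <- list(layout$ids, c(bx_ids, ctl_ids))
  expr <- expression_matrix(vals, ctl_ids)

  # donor age: configured Pearson coupling to standardized z3
  am <- cfg$age_model
  z3s <- as.vector(scale(z[, 3]))
  age <- am$mean + am$sd * (am$coupling * z3s +
                              sqrt(1 - am$coupling^2) * stats::rnorm(n))
  age <- pmin(pmax(age, am$range[1]), am$range[2])

  em <- cfg$egfr_model
  egfr <- em$base + em$slope_z1 * z[, 1] + em$slope_z2 * z[, 2] +
    em$slope_z3 * z[, 3] + stats::rnorm(n, 0, em$noise_sd)
  egfr <- pmax(egfr, em$floor)

  ph <- cfg$pheno_model
  prot <- stats::rbinom(n, 1, stats::plogis(ph$prot_intercept +
                                              ph$prot_z1 * z[, 1] +
                                              ph$prot_z2 * z[, 2]))
  u_ci <- z[, 2] + stats::rnorm(n, 0, ph$lesion_noise_sd)
  u_ct <- z[, 2] + stats::rnorm(n, 0, ph$lesion_noise_sd)
  ci <- findInterval(u_ci, ph$ci_cuts)
  ct <- findInterval(u_ct, ph$ct_cuts)

  cortex <- stats::runif(n, ph$cortex_range[1], ph$cortex_range[2])
  low <- stats::runif(n) < ph$low_cortex_frac
  cortex[low] <- stats::runif(sum(low), 0, 10)

  # kidneys: some have repeat biopsies
  n_kidneys <- max(1L, ceiling(n / ph$biopsies_per_kidney))
  kidney <- sprintf("K%05d", sample.int(n_kidneys, n, replace = TRUE))

  # death-censored survival anchored at the biopsy
  hz <- cfg$hazard_params
  lhr <- (hz$b1 + hz$b1_time_slope * (logt - log(365))) * z[, 1] + hz$b3 * z[, 3]
  t_fail <- stats::rexp(n, rate = hz$h0 * exp(lhr))
  t_death <- stats::rexp(n, rate = hz$death_rate)
  t_admin <- stats::runif(n, hz$admin_range[1], hz$admin_range[2])
  fup <- pmin(t_fail, t_death, t_admin)
  failed <- as.integer(t_fail <= pmin(t_death, t_admin))
  died <- as.integer(t_death < pmin(t_fail, t_admin))
  has_fup <- stats::runif(n) < ph$followup_frac
  fup[!has_fup] <- NA
  failed[!has_fup] <- NA
  died[!has_fup] <- NA

  meta <- data.frame(
    sample_id = bx_ids, kidney_id = kidney,
    txbx_days = txbx, egfr = egfr, donor_age = age,
    proteinuria_pos = prot, ci_score = ci, ct_score = ct,
    pct_cortex = cortex, rejection_group = "no rejection",
    followup_days = fup, graft_failed = failed, died_with_function = died,
    stringsAsFactors = FALSE
  )
  meta <- validate_metadata(meta)

  ann <- c(setNames(rep("input-PBT", 6), input_pbt_names()),
           setNames(rep("new-gene-set", 12), new_set_names()))
  sets <- structure(layout$sets,
                    description = setNames(ann[names(layout$sets)], names(layout$sets)),
                    annotation = ann[names(layout$sets)],
                    class = "gene_set_collection")

  truth <- data.frame(sample_id = bx_ids, z1 = z[, 1], z2 = z[, 2], z3 = z[, 3],
                      true_state_label = state, true_hazard = exp(lhr),
                      stringsAsFactors = FALSE)

  list(expr = expr, meta = meta, sets = sets, truth = truth,
       mki67_probe = layout$mki67)
}

#' Generate control (nephrectomy) samples only
#'
#' Controls are drawn from the baseline expression model with all latent
#' axes fixed at zero. The baseline, loading jitter and probe layout are the
#' same as [generate_cohort()] would produce for this config.
#'
#' @param config A [cohort_config()].
#' @return An [expression_matrix()] of `n_controls` columns, all controls.
#' @export
generate_controls <- function(config) {
  cfg <- validate_cohort_config(config)
  if (cfg$n_controls < 1) stop("n_controls must be >= 1", call. = FALSE)
  lp <- cfg$latent_params
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))
  layout <- probe_layout(cfg)
  baseline <- stats::rnorm(cfg$n_probesets, lp$baseline_mean, lp$baseline_sd)
  ctl_ids <- sprintf("CTL%d", seq_len(cfg$n_controls))
  vals <- baseline + matrix(stats::rnorm(cfg$n_probesets * cfg$n_controls,
                                         0, lp$noise_sd),
                            cfg$n_probesets, cfg$n_controls)
  dimnames(vals) <- list(layout$ids, ctl_ids)
  expression_matrix(vals, ctl_ids)
}

#' Simulate death-censored survival from a linear predictor
#'
#' Inverse-transform sampling from an exponential failure hazard
#' `h0 * exp(lp)` with an independent exponential death process and uniform
#' administrative censoring; the building block the cohort generator uses,
#' exposed for survival-model recovery simulations.
#'
#' @param lp Numeric vector, per-subject log-hazard (linear predictor).
#' @param h0 Baseline daily hazard.
#' @param death_rate Daily hazard of death with function.
#' @param admin_range Administrative censoring window (days), uniform.
#' @param seed Integer seed.
#' @return data.frame with `followup_days`, `graft_failed`,
#'   `died_with_function`.
#' @export
simulate_survival <- function(lp, h0 = 1.5e-4, death_rate = 6e-5,
                              admin_range = c(365, 3650), seed = 1) {
  n <- length(lp)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  t_fail <- stats::rexp(n, rate = h0 * exp(lp))
  t_death <- if (death_rate > 0) stats::rexp(n, rate = death_rate) else rep(Inf, n)
  t_admin <- stats::runif(n, admin_range[1], admin_range[2])
  data.frame(
    followup_days = pmin(t_fail, t_death, t_admin),
    graft_failed = as.integer(t_fail <= pmin(t_death, t_admin)),
    died_with_function = as.integer(t_death < pmin(t_fail, t_admin))
  )
}
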