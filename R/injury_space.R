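#' Correlation PCA of the ten standardized injury scores
#'
#' Eigendecomposition of the correlation matrix of the model inputs. All
#' components are retained; the first three carry the model's
#' interpretation (global injury + inflammation, time-posttransplant
#' contrast, epithelial remodeling).
#'
#' @param table Standardized `score_table` (or data.frame); only the model
#'   input columns enter the fit.
#' @param input_cols Columns to decompose; default [input_columns()] of the
#'   table, else all columns.
#' @return An `injury_pca` list: `loadings` (p x p orthonormal),
#'   `eigenvalues`, `variance_fractions`, `scores` (n x p), `center`,
#'   `scale`, `orientation` (per-PC sign record), `input_cols`.
#' @export
fit_pca <- function(table, input_cols = NULL) {
  if (is.null(input_cols)) input_cols <- input_columns(table) %||% names(table)
  x <- as.matrix(as.data.frame(table)[input_cols])
  p <- ncol(x)
  if (nrow(x) <= p) stop("need more biopsies than input columns", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  if (min(ev) < 1e-10 * max(ev)) {
    warning("input score matrix is (near) rank deficient", call. = FALSE)
  }
  structure(list(loadings = pc$rotation, eigenvalues = ev,
                 variance_fractions = ev / sum(ev),
                 scores = pc$x, center = pc$center, scale = pc$scale,
                 orientation = rep(1, p), input_cols = input_cols),
            class = "injury_pca")
}

#' @export
print.injury_pca <- function(x, ...) {
  vf <- round(100 * x$variance_fractions[1:min(3, length(x$variance_fractions))], 1)
  cat(sprintf("injury_pca: %d inputs, %d biopsies; PC1/2/3 variance %s%%\n",
              ncol(x$loadings), nrow(x$scores), paste(vf, collapse = "/")))
  invisible(x)
}

#' Project new biopsies onto a fitted PCA
#' @param pca An `injury_pca`.
#' @param table Table containing the model input columns (same scale as the
#'   training table before the internal centering/scaling).
#' @return Matrix of PC scores.
#' @export
pca_project <- function(pca, table) {
  x <- as.matrix(as.data.frame(table)[pca$input_cols])
  scale(x, pca$center, pca$scale) %*% pca$loadings
}

# orientation statistics: each returns a signed number whose sign fixes the PC
aki_set_names <- function() c("IRRAT30", "IRITD3", "IRITD5", "DAMP")
ckd_contrast_names <- function() c("MCAT", "IGT", "ci_gt1_Prob", "ct_gt1_Prob")

#' Deterministically orient principal components
#'
#' Signs of eigenvectors are arbitrary; the model fixes them so the
#' components carry their interpretation: PC1 correlates positively with
#' the mean of all ten input scores (global injury); PC2 correlates
#' positively with the CKD-minus-AKI score contrast (mean of MCAT, IGT,
#' ci>1_Prob, ct>1_Prob minus mean of IRRAT30, IRITD3, IRITD5, DAMP); PC3
#' has a positive lowGFR_Prob loading. Applying the rules twice is a no-op.
#'
#' @param pca An `injury_pca`.
#' @param table The (standardized) score table the model was fitted on.
#' @return The oriented model, with the accumulated sign flips recorded in
#'   `$orientation`.
#' @export
orient_pcs <- function(pca, table) {
  df <- as.data.frame(table)
  stat <- c(
    stats::cor(rowMeans(df[pca$input_cols]), pca$scores[, 1]),
    stats::cor(rowMeans(df[intersect(ckd_contrast_names(), pca$input_cols)]) -
                 rowMeans(df[intersect(aki_set_names(), pca$input_cols)]),
               pca$scores[, 2]),
    pca$loadings["lowGFR_Prob", 3]
  )
  for (j in 1:3) {
    if (stat[j] == 0) {
      warning(sprintf("orientation statistic for PC%d is exactly zero; sign kept", j),
              call. = FALSE)
    } else if (stat[j] < 0) {
      pca$loadings[, j] <- -pca$loadings[, j]
      pca$scores[, j] <- -pca$scores[, j]
      pca$orientation[j] <- -pca$orientation[j]
    }
  }
  pca
}

# ---- archetypal analysis ------------------------------------------------

# Exact simplex-constrained least squares for each row of X against the
# rows of Z (k archetypes): enumerate supports, solve the sum-to-one
# equality-constrained problem in closed form, keep the feasible solution
# with minimal RSS. Exact by KKT for small k.
simplex_weights <- function(X, Z, tol = 1e-9) {
  n <- nrow(X); k <- nrow(Z)
  if (ncol(X) != ncol(Z)) stop("dimensionality mismatch", call. = FALSE)
  if (k > 12) return(simplex_weights_nnls(X, Z))
  G <- Z %*% t(Z)
  M <- Z %*% t(X)                       # k x n
  xnorm <- rowSums(X^2)
  best_rss <- rep(Inf, n)
  best_a <- matrix(0, n, k)
  supports <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  for (S in supports) {
    s <- length(S)
    Gs <- G[S, S, drop = FALSE] + diag(1e-10, s)
    Gi <- tryCatch(solve(Gs), error = function(e) NULL)
    if (is.null(Gi)) next
    c1 <- Gi %*% rep(1, s)
    denom <- sum(c1)
    if (abs(denom) < 1e-12) next
    A0 <- Gi %*% M[S, , drop = FALSE]   # s x n unconstrained (in span) part
    lam <- (1 - colSums(A0)) / denom
    A <- A0 + c1 %*% t(lam)             # s x n, columns sum to 1
    feas <- colSums(A < -tol) == 0
    if (!any(feas)) next
    GA <- G[S, S, drop = FALSE] %*% A
    rss <- xnorm - 2 * colSums(A * M[S, , drop = FALSE]) + colSums(A * GA)
    upd <- feas & rss < best_rss - 1e-12
    if (any(upd)) {
      best_rss[upd] <- rss[upd]
      best_a[upd, ] <- 0
      best_a[upd, S] <- t(A[, upd, drop = FALSE])
    }
  }
  a <- pmax(best_a, 0)
  a <- a / rowSums(a)
  list(weights = a, rss = pmax(best_rss, 0))
}

# furthest-point traversal: greedy selection of k mutually distant points,
# starting from the point furthest from a random anchor
furthest_points <- function(X, k, start) {
  d0 <- rowSums(sweep(X, 2, X[start, ])^2)
  chosen <- which.max(d0)
  mind <- rowSums(sweep(X, 2, X[chosen, ])^2)
  while (length(chosen) < k) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, rowSums(sweep(X, 2, X[nxt, ])^2))
  }
  chosen
}

# worst simplex-constraint violation across both weight matrices, recorded
# per iteration so tests can assert feasibility throughout the fit
simplex_violation <- function(A, B) {
  max(abs(rowSums(A) - 1), abs(rowSums(B) - 1), -min(A), -min(B), 0)
}

# fallback for larger k: penalized NNLS per row
simplex_weights_nnls <- function(X, Z) {
  w <- 200 * max(abs(Z), 1)
  C <- rbind(t(Z), w)
  a <- t(apply(X, 1, function(x) nnls_lh(C, c(x, w))))
  a <- a / rowSums(a)
  resid <- X - a %*% Z
  list(weights = a, rss = rowSums(resid^2))
}

# Lawson-Hanson non-negative least squares (small dense problems);
# gradient tolerance is relative to the initial gradient scale, so the
# stopping rule is invariant to the scaling of C and d
nnls_lh <- function(C, d, tol = NULL, max_iter = 3 * nrow(C) + 30) {
  n <- ncol(C)
  P <- logical(n)
  x <- numeric(n)
  w <- crossprod(C, d)
  if (is.null(tol)) tol <- 1e-10 * max(abs(w), 1)
  for (it in seq_len(max_iter)) {
    cand <- which(!P & w > tol)
    if (!length(cand)) break
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- qr.coef(qr(C[, P, drop = FALSE]), d)
      s[is.na(s)] <- 0
      wtol <- 1e-12
      if (all(s[P] > wtol)) { x <- s; break }
      bad <- P & s <= wtol
      alpha <- min(x[bad] / (x[bad] - s[bad]))
      x <- x + alpha * (s - x)
      P[P & x <= wtol] <- FALSE
      x[!P] <- 0
    }
    w <- crossprod(C, d - C %*% x)
  }
  x
}

#' Archetypal analysis by alternating constrained least squares
#'
#' Represents each biopsy as a convex combination of `k` archetypes that
#' are themselves convex combinations of biopsies (Cutler-Breiman sense).
#' Each iteration solves the sample-weight problem exactly (simplex-
#' constrained least squares per biopsy), then proposes an archetype update
#' (unconstrained solve followed by projection of each archetype into the
#' convex hull of the data by penalized non-negative least squares); the
#' proposal is accepted only if it lowers the residual sum of squares, so
#' the RSS trace is non-increasing by construction. Best of `n_restarts`
#' random initializations is kept; fully seed-deterministic.
#'
#' @param X Numeric matrix, biopsies x dimensions (standardized input
#'   scores by default in this model; PC scores also work).
#' @param k Number of archetypes (default 5).
#' @param n_restarts Random restarts (default 10).
#' @param tol Relative RSS change declaring convergence.
#' @param max_iter Maximum alternations per restart.
#' @param seed Integer seed.
#' @return An `archetype_model`: `archetypes` (k x d), `alpha` (n x k sample
#'   weights), `beta` (k x n archetype composition weights), `rss`,
#'   `rss_trace` and `constraint_violation` (per accepted iteration, best
#'   restart), `converged`, `restart`, `labels` (NULL until
#'   [label_archetypes()]).
#' @export
fit_archetypes <- function(X, k = 5, n_restarts = 10, tol = 1e-6,
                           max_iter = 500, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of biopsies", call. = FALSE)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  w_pen <- 200 * max(abs(X), 1)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # first restart seeds archetypes at mutually distant extreme points
    # (furthest-point traversal); later restarts are random
    init <- if (r == 1) furthest_points(X, k, start = sample.int(n, 1))
            else sample.int(n, k)
    B <- matrix(0, k, n)
    B[cbind(seq_len(k), init)] <- 1
    Z <- B %*% X
    sw <- simplex_weights(X, Z)
    A <- sw$weights
    rss <- sum(sw$rss)
    trace <- rss
    viol <- simplex_violation(A, B)
    converged <- FALSE
    Cmat <- rbind(t(X), w_pen)
    for (it in seq_len(max_iter)) {
      # archetype update: exact cyclic coordinate descent. With A fixed, the
      # optimal z_j (unconstrained) is the weighted residual mean
      # a_j'R_j / ||a_j||^2 where R_j excludes archetype j; constraining z_j
      # to the convex hull of the data reduces to a simplex regression of
      # that target onto the biopsies
      B_new <- B
      Z_new <- Z
      fitted <- A %*% Z_new
      for (j in seq_len(k)) {
        aj <- A[, j]
        s2 <- sum(aj^2)
        if (s2 < 1e-12) {
          # archetype carries no weight: reseed at the worst-fitted biopsy
          worst <- which.max(rowSums((X - fitted)^2))
          b <- numeric(n); b[worst] <- 1
        } else {
          Rj_target <- crossprod(X - fitted, aj) / s2 + Z_new[j, ]
          b <- nnls_lh(Cmat, c(Rj_target, w_pen))
          sb <- sum(b)
          if (sb <= 0) { b <- numeric(n); b[init[j]] <- 1 } else b <- b / sb
        }
        z_old <- Z_new[j, ]
        B_new[j, ] <- b
        Z_new[j, ] <- as.numeric(b %*% X)
        fitted <- fitted + outer(aj, Z_new[j, ] - z_old)
      }
      # backtracking line search on B: convex combinations of row-stochastic
      # matrices stay row-stochastic, so every damped step is feasible
      step <- 1
      accepted <- FALSE
      while (step >= 1 / 16) {
        B_try <- (1 - step) * B + step * B_new
        Z_try <- B_try %*% X
        sw_try <- simplex_weights(X, Z_try)
        rss_try <- sum(sw_try$rss)
        if (rss_try <= rss) {
          Z <- Z_try; B <- B_try; A <- sw_try$weights
          improved <- rss - rss_try
          trace <- c(trace, rss_try)
          viol <- c(viol, simplex_violation(A, B))
          rss <- rss_try
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) { converged <- TRUE; break }     # no descent step left
      if (improved <= tol * max(rss, 1e-12)) { converged <- TRUE; break }
    }
    if (is.null(best) || rss < best$rss) {
      best <- list(archetypes = Z, alpha = A, beta = B, rss = rss,
                   rss_trace = trace, constraint_violation = viol,
                   converged = converged, restart = r)
    }
  }
  if (!best$converged) {
    warning("archetypal analysis did not converge in any restart; best fit returned",
            call. = FALSE)
  }
  colnames(best$archetypes) <- colnames(X)
  rownames(best$alpha) <- rownames(X)
  best$labels <- NULL
  class(best) <- "archetype_model"
  best
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(sprintf("archetype_model: k=%d, RSS=%.4g, %d iterations (restart %d)%s\n",
              nrow(x$archetypes), x$rss, length(x$rss_trace), x$restart,
              if (is.null(x$labels)) "" else paste0("; labels: ",
                                                    paste(x$labels, collapse = ", "))))
  invisible(x)
}

#' Archetype scores for (new) biopsies
#'
#' Simplex-constrained least-squares weight of each biopsy on each fixed
#' archetype: the biopsy's proximity to each archetype center.
#'
#' @param model An `archetype_model`.
#' @param X Biopsies x dimensions matrix in the model's space.
#' @return n x k matrix of non-negative weights, each row summing to 1.
#' @export
archetype_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$archetypes)) stop("dimensionality mismatch", call. = FALSE)
  w <- simplex_weights(X, model$archetypes)$weights
  rownames(w) <- rownames(X)
  colnames(w) <- model$labels %||% paste0("A", seq_len(nrow(model$archetypes)))
  w
}

#' Assign each biopsy to its highest-scoring archetype
#'
#' Argmax over the archetype scores; exact ties go to the lowest archetype
#' index, so assignment is deterministic.
#'
#' @param scores n x k matrix of archetype weights.
#' @return Character vector of column labels (or `A<j>` indices).
#' @export
assign_group <- function(scores) {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("non-finite archetype scores", call. = FALSE)
  labs <- colnames(scores) %||% paste0("A", seq_len(ncol(scores)))
  idx <- apply(scores, 1, which.max)  # which.max takes the first maximum
  setNames(labs[idx], rownames(scores))
}

#' Label the five archetypes from their injury features
#'
#' Deterministic rules on the archetype centroids in (standardized) input-
#' score space: `normal` has the lowest mean of the ten inputs; of the
#' rest, the two with the highest AKI contrast (mean AKI-set scores minus
#' mean CKD-set scores) are the AKI archetypes, `AKI2` being the one with
#' the higher PC1 centroid; of the remaining two, `CKDAKI` has the higher
#' mean AKI-set scores and `mildCKD` is the other.
#'
#' @param model A fitted `archetype_model` in standardized input space
#'   (k = 5).
#' @param pca Optional oriented `injury_pca` used for the PC1 centroid;
#'   without it the mean of the ten inputs is the PC1 proxy.
#' @return The model with `$labels` set (archetype index -> label).
#' @export
label_archetypes <- function(model, pca = NULL) {
  Z <- model$archetypes
  if (nrow(Z) != 5) stop("labeling rules require k = 5 archetypes", call. = FALSE)
  inputs <- c(input_pbt_names(), classifier_prob_names())
  if (!all(inputs %in% colnames(Z))) {
    stop("archetypes must live in input-score space (10 named columns)", call. = FALSE)
  }
  mean10 <- rowMeans(Z[, inputs, drop = FALSE])
  aki_mean <- rowMeans(Z[, aki_set_names(), drop = FALSE])
  ckd_mean <- rowMeans(Z[, ckd_contrast_names(), drop = FALSE])
  contrast <- aki_mean - ckd_mean
  pc1 <- if (!is.null(pca)) {
    as.numeric(scale(Z[, pca$input_cols], pca$center, pca$scale) %*% pca$loadings[, 1])
  } else mean10
  labels <- character(5)
  normal <- which.min(mean10)
  labels[normal] <- "normal"
  rest <- setdiff(1:5, normal)
  aki_pair <- rest[order(contrast[rest], decreasing = TRUE)[1:2]]
  labels[aki_pair[which.max(pc1[aki_pair])]] <- "AKI2"
  labels[setdiff(aki_pair, aki_pair[which.max(pc1[aki_pair])])] <- "AKI1"
  ckd_pair <- setdiff(rest, aki_pair)
  ckdaki <- ckd_pair[which.max(aki_mean[ckd_pair])]
  labels[ckdaki] <- "CKDAKI"
  labels[setdiff(ckd_pair, ckdaki)] <- "mildCKD"
  if (anyDuplicated(labels)) {
    stop("labeling rules produced a non-bijective assignment; centroids:\n",
         paste(utils::capture.output(print(round(Z, 3))), collapse = "\n"),
         call. = FALSE)
  }
  model$labels <- labels
  model
}

# ---- factor map / supplementary projection ------------------------------

#' Project variables onto the factor map as supplementary variables
#'
#' A variable's coordinate on PC j is its Pearson correlation with the
#' PC-j scores; the variable never influences the fit. For a model input
#' this equals `loading_j * sqrt(eigenvalue_j)` (correlation-PCA identity).
#'
#' @param pca An `injury_pca`.
#' @param variables Data frame or matrix of per-biopsy variables, rows
#'   aligned with the model's biopsies.
#' @param pcs PC indices to report (default 1:3).
#' @return Data frame: one row per variable, columns `PC<j>` in \[-1, 1\].
#' @export
project_supplementary <- function(pca, variables, pcs = 1:3) {
  v <- as.matrix(as.data.frame(variables))
  if (nrow(v) != nrow(pca$scores)) stop("variable not defined on the model's biopsies", call. = FALSE)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  }
  co <- stats::cor(v, pca$scores[, pcs, drop = FALSE])
  out <- as.data.frame(co)
  names(out) <- paste0("PC", pcs)
  out
}

#' Top genes correlating with each principal component
#'
#' Spearman correlation of every probe set with the PC scores; the `top_n`
#' most positive and most negative probes per component, ties broken by
#' probe id for determinism.
#'
#' @param expr An [expression_matrix()] whose biopsy columns match the PCA
#'   rows.
#' @param pca An `injury_pca`.
#' @param pcs PC indices (default 1:3).
#' @param top_n List length per direction (default 200).
#' @return Named list per PC with data.frames `positive` and `negative`
#'   (`probe_id`, `rho`), sorted by signed rho.
#' @export
pc_gene_correlations <- function(expr, pca, pcs = 1:3, top_n = 200) {
  bx <- rownames(pca$scores)
  if (is.null(bx)) bx <- biopsy_ids(expr)
  if (length(bx) < 3) stop("need at least 3 biopsies", call. = FALSE)
  x <- expr$values[, bx, drop = FALSE]
  rx <- t(apply(x, 1, rank))
  rs <- apply(pca$scores[, pcs, drop = FALSE], 2, rank)
  co <- stats::cor(t(rx), rs)   # Pearson of ranks = Spearman
  lapply(setNames(seq_along(pcs), paste0("PC", pcs)), function(j) {
    rho <- co[, j]
    ord_pos <- order(-rho, rownames(co))
    ord_neg <- order(rho, rownames(co))
    n_take <- min(top_n, length(rho))
    list(
      positive = data.frame(probe_id = rownames(co)[ord_pos[1:n_take]],
                            rho = rho[ord_pos[1:n_take]], row.names = NULL),
      negative = data.frame(probe_id = rownames(co)[ord_neg[1:n_take]],
                            rho = rho[ord_neg[1:n_take]], row.names = NULL)
    )
  })
}

#' Seed-deterministic 2-D embedding of the score table
#'
#' Neighbor-graph embedding for visualization only: a symmetrized k-nearest-
#' neighbor graph over the standardized inputs laid out with the
#' Fruchterman-Reingold algorithm from a PCA initialization under a fixed
#' seed. Never used in inference.
#'
#' @param table Standardized score table (inputs only are used).
#' @param seed Integer seed.
#' @param n_neighbors Neighbors per biopsy (default 15).
#' @param n_iter Layout iterations.
#' @return n x 2 coordinate matrix.
#' @export
embed_2d <- function(table, seed = 1, n_neighbors = 15, n_iter = 500) {
  cols <- input_columns(table) %||% names(table)
  x <- as.matrix(as.data.frame(table)[cols])
  n <- nrow(x)
  if (n < 10) stop("need at least 10 biopsies to embed", call. = FALSE)
  k <- min(n_neighbors, n - 1)
  d <- as.matrix(stats::dist(x))
  nb <- t(apply(d, 1, function(row) order(row)[2:(k + 1)]))
  edges <- cbind(rep(seq_len(n), k), as.vector(nb))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  init <- stats::prcomp(x, rank. = 2)$x
  init <- init / max(abs(init))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  coords <- igraph::layout_with_fr(g, coords = init, niter = n_iter)
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

# ---- model serialization ------------------------------------------------

#' Serialize / restore the fitted injury model (PCA + archetypes)
#'
#' JSON with loadings, eigenvalues, centering/scaling, orientation record,
#' archetypes, composition weights and labels; per-biopsy outputs are
#' written separately as CSV by the caller.
#'
#' @param pca An `injury_pca`.
#' @param arch An `archetype_model`.
#' @param path JSON path.
#' @return `path` / list with restored `pca` and `arch` (without per-biopsy
#'   scores).
#' @export
write_injury_model <- function(pca, arch, path) {
  obj <- list(
    pca = list(loadings = pca$loadings, eigenvalues = pca$eigenvalues,
               variance_fractions = pca$variance_fractions,
               center = pca$center, scale = pca$scale,
               orientation = pca$orientation, input_cols = pca$input_cols),
    archetypes = list(centers = arch$archetypes, labels = arch$labels,
                      rss = arch$rss, restart = arch$restart)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_injury_model
#' @export
read_injury_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$pca
  cols <- p$input_cols
  loadings <- as.matrix(p$loadings)
  dimnames(loadings) <- list(cols, paste0("PC", seq_along(cols)))
  pca <- structure(list(loadings = loadings,
                        eigenvalues = p$eigenvalues,
                        variance_fractions = p$variance_fractions,
                        scores = NULL,
                        center = setNames(unlist(p$center), cols),
                        scale = setNames(unlist(p$scale), cols),
                        orientation = p$orientation, input_cols = cols),
                   class = "injury_pca")
  centers <- as.matrix(obj$archetypes$centers)
  dimnames(centers) <- list(NULL, cols)
  arch <- structure(list(archetypes = centers, labels = obj$archetypes$labels,
                         rss = obj$archetypes$rss,
                         restart = obj$archetypes$restart),
                    class = "archetype_model")
  list(pca = pca, arch = arch)
}
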