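test_that("PCA equals brute-force eigendecomposition of the correlation matrix", {
  set.seed(10)
  for (i in 1:5) {
    x <- as.data.frame(matrix(rnorm(20 * 10), 20, 10))
    names(x) <- paste0("v", 1:10)
    fit <- fit_pca(x, input_cols = names(x))
    eig <- eigen(cor(x), symmetric = TRUE)
    expect_equal(fit$eigenvalues, eig$values, tolerance = 1e-8)
    for (j in 1:10) {
      expect_lt(min(sum(abs(fit$loadings[, j] - eig$vectors[, j])),
                    sum(abs(fit$loadings[, j] + eig$vectors[, j]))), 1e-6)
    }
    expect_equal(sum(fit$variance_fractions), 1, tolerance = 1e-12)
  }
})

test_that("PCA handles degenerate shapes as specified", {
  # two perfectly correlated columns -> PC1 carries all variance
  x <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = 2 * c(1, 2, 3, 4, 5, 6))
  expect_warning(fit <- fit_pca(x, input_cols = c("a", "b")), "rank deficient")
  expect_equal(fit$variance_fractions[1], 1, tolerance = 1e-10)
  # n <= p rejected
  expect_error(fit_pca(as.data.frame(matrix(rnorm(30), 3, 10))), "more biopsies")
})

test_that("PC scores reproduce the standardized data within discarded eigenvalue mass", {
  set.seed(11)
  x <- as.data.frame(matrix(rnorm(50 * 6), 50, 6))
  fit <- fit_pca(x, input_cols = names(x))
  xs <- scale(as.matrix(x))
  for (k in c(2, 4)) {
    recon <- fit$scores[, 1:k] %*% t(fit$loadings[, 1:k])
    expect_equal(sum((xs - recon)^2) / (nrow(x) - 1),
                 sum(fit$eigenvalues[(k + 1):6]), tolerance = 1e-8)
  }
})

test_that("orientation rules are idempotent and undo deliberate sign flips", {
  rm <- reference_model()
  pca <- rm$fit$pca
  std <- rm$fit$scores
  expect_identical(orient_pcs(pca, std)$loadings, pca$loadings)  # idempotent
  flipped <- pca
  for (j in 1:3) {
    flipped$loadings[, j] <- -flipped$loadings[, j]
    flipped$scores[, j] <- -flipped$scores[, j]
    flipped$orientation[j] <- -flipped$orientation[j]
  }
  back <- orient_pcs(flipped, std)
  expect_equal(back$loadings[, 1:3], pca$loadings[, 1:3])
  expect_equal(back$orientation[1:3], pca$orientation[1:3])
})

test_that("a single archetype is the column-mean vector", {
  set.seed(12)
  X <- matrix(rnorm(40 * 3), 40, 3)
  fit <- fit_archetypes(X, k = 1, n_restarts = 3, seed = 1)
  expect_lt(max(abs(fit$archetypes[1, ] - colMeans(X))), 1e-6)
  # cross-check on a 5-point toy against a dense search over hull points
  X5 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0.5, 0.5), 5, 2, byrow = TRUE)
  f5 <- fit_archetypes(X5, k = 1, n_restarts = 3, seed = 1)
  w <- seq(0, 1, by = 0.05)
  grid <- as.matrix(expand.grid(w, w, w, w))
  grid <- grid[abs(rowSums(grid)) > 0, , drop = FALSE]
  grid <- cbind(grid, pmax(1 - rowSums(grid), 0))
  grid <- grid / rowSums(grid)
  cand <- grid %*% X5
  rss <- apply(cand, 1, function(z) sum(sweep(X5, 2, z)^2))
  expect_lte(sum(sweep(X5, 2, f5$archetypes[1, ])^2), min(rss) + 1e-8)
})

test_that("noiseless vertices are recovered exactly", {
  verts <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  X <- verts[rep(1:3, each = 10), ]
  fit <- fit_archetypes(X, k = 3, n_restarts = 5, seed = 2)
  expect_lt(fit$rss, 1e-8)
  expect_lt(max(match_vertices(fit$archetypes, verts)), 1e-4)
})

test_that("the RSS trace never increases and weights stay on the simplex", {
  set.seed(13)
  X <- matrix(rnorm(300 * 4), 300, 4)
  fit <- fit_archetypes(X, k = 4, n_restarts = 3, seed = 3)
  expect_true(all(diff(fit$rss_trace) <= 1e-10))
  expect_lt(max(fit$constraint_violation), 1e-8)
  expect_equal(unname(rowSums(fit$alpha)), rep(1, 300), tolerance = 1e-8)
  expect_true(min(fit$alpha) >= -1e-12)
  expect_equal(unname(rowSums(fit$beta)), rep(1, 4), tolerance = 1e-8)
  expect_true(min(fit$beta) >= -1e-12)
  expect_error(fit_archetypes(X[1:3, ], k = 5), "smaller")
})

test_that("archetype scores solve the simplex least-squares problem", {
  verts <- matrix(c(0, 0, 4, 0, 0, 4), 3, 2, byrow = TRUE)
  model <- structure(list(archetypes = verts, labels = NULL),
                     class = "archetype_model")
  # a biopsy at an archetype gets weight 1 on it
  s <- archetype_scores(model, verts)
  expect_equal(unname(s), diag(3), tolerance = 1e-10)
  # midpoint of two archetypes in 1-D: weights (0.5, 0.5)
  m2 <- structure(list(archetypes = matrix(c(0, 2), 2, 1), labels = NULL),
                  class = "archetype_model")
  expect_equal(unname(archetype_scores(m2, matrix(1, 1, 1))), matrix(0.5, 1, 2),
               tolerance = 1e-10)
  # random points vs a dense simplex grid search (k = 3, resolution 0.01)
  set.seed(14)
  pts <- matrix(rnorm(6 * 2, sd = 2), 6, 2)
  got <- archetype_scores(model, pts)
  w <- seq(0, 1, by = 0.01)
  grid <- as.matrix(expand.grid(a = w, b = w))
  grid <- grid[rowSums(grid) <= 1, ]
  grid <- cbind(grid, c = 1 - rowSums(grid))
  cand <- grid %*% verts
  for (i in seq_len(nrow(pts))) {
    grid_rss <- min(colSums((t(cand) - pts[i, ])^2))
    my_rss <- sum((pts[i, ] - got[i, ] %*% verts)^2)
    expect_lte(my_rss, grid_rss + 1e-6)
  }
  expect_error(archetype_scores(model, matrix(0, 1, 3)), "mismatch")
})

test_that("group assignment is argmax with deterministic tie-breaking", {
  s <- rbind(c(0.6, 0.1, 0.1, 0.1, 0.1),
             c(0.5, 0.5, 0, 0, 0))
  colnames(s) <- paste0("A", 1:5)
  g <- assign_group(s)
  expect_equal(unname(g), c("A1", "A1"))   # tie goes to the lowest index
  expect_error(assign_group(rbind(c(NA, 1))), "non-finite")
})

test_that("archetype labeling follows the centroid rules and is order-invariant", {
  rm <- reference_model()
  arch <- rm$fit$arch
  expect_setequal(arch$labels, c("normal", "AKI1", "AKI2", "mildCKD", "CKDAKI"))
  # permuting archetype order permutes labels consistently
  perm <- c(3, 1, 5, 2, 4)
  arch2 <- arch
  arch2$archetypes <- arch$archetypes[perm, ]
  arch2$labels <- NULL
  relab <- label_archetypes(arch2, rm$fit$pca)
  expect_equal(relab$labels, arch$labels[perm])
  # k != 5 rejected
  bad <- arch; bad$archetypes <- arch$archetypes[1:4, ]
  expect_error(label_archetypes(bad), "k = 5")
})

test_that("labeled groups match the planted state semantics", {
  rm <- reference_model()
  tab <- table(rm$fit$groups, rm$truth$true_state_label)
  # each assigned group's most common planted state is its namesake
  for (g in c("normal", "AKI1", "AKI2", "mildCKD", "CKDAKI")) {
    expect_equal(colnames(tab)[which.max(tab[g, ])], g)
  }
})

test_that("supplementary projection satisfies the correlation-PCA identities", {
  rm <- reference_model()
  pca <- rm$fit$pca
  std <- as.data.frame(rm$fit$scores)
  # projecting PC1 scores themselves -> (1, 0, 0)
  co <- project_supplementary(pca, data.frame(pc1 = pca$scores[, 1]))
  expect_equal(unname(as.matrix(co)), matrix(c(1, 0, 0), 1), tolerance = 1e-8)
  # projecting an input column equals loading * sqrt(eigenvalue)
  co2 <- project_supplementary(pca, std["IRRAT30"])
  expect_equal(as.numeric(co2),
               pca$loadings["IRRAT30", 1:3] * sqrt(pca$eigenvalues[1:3]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # negation flips coordinates
  co3 <- project_supplementary(pca, data.frame(neg = -std$IRRAT30))
  expect_equal(as.numeric(co3), -as.numeric(co2), tolerance = 1e-12)
  expect_error(project_supplementary(pca, data.frame(k = rep(1, nrow(std)))),
               "constant")
})

test_that("top PC-correlated genes are ranked by Spearman rho with stable ties", {
  set.seed(15)
  n <- 30
  scores <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("B", 1:n), NULL))
  pca <- structure(list(scores = scores), class = "injury_pca")
  vals <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(sprintf("g%02d", 1:10), rownames(scores)))
  vals[1, ] <- scores[, 1]          # probe equal to PC1 -> rho 1, ranked first
  expr <- expression_matrix(vals)
  res <- pc_gene_correlations(expr, pca, top_n = 200)
  expect_equal(res$PC1$positive$probe_id[1], "g01")
  expect_equal(res$PC1$positive$rho[1], 1)
  expect_equal(nrow(res$PC1$positive), 10)  # top_n larger than probe count
  # ordering agrees with brute-force rank correlation
  brute <- apply(vals, 1, function(g) spearman_brute(g, scores[, 1]))
  expect_equal(res$PC1$positive$probe_id, names(sort(-brute)))
})

test_that("the 2-D embedding is seed-deterministic with shape n x 2", {
  rm <- reference_model()
  std <- rm$fit$scores[1:80, ]
  e1 <- embed_2d(std, seed = 5)
  e2 <- embed_2d(std, seed = 5)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(80, 2))
  expect_error(embed_2d(std[1:5, ], seed = 1), "at least 10")
})

test_that("the fitted injury model serializes and projects after reload", {
  rm <- reference_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_injury_model(rm$fit$pca, rm$fit$arch, path)
  back <- read_injury_model(path)
  expect_equal(back$pca$loadings, rm$fit$pca$loadings, tolerance = 1e-12)
  expect_equal(back$arch$labels, rm$fit$arch$labels)
  # projection with the reloaded model reproduces the original scores
  proj <- pca_project(back$pca, rm$fit$scores)
  expect_equal(unname(proj[, 1:3]), unname(rm$fit$pca$scores[, 1:3]),
               tolerance = 1e-8)
})
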