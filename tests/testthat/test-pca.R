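test_that("region z-scoring follows the sample-SD convention", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 8, 6))
  z <- zscore_regions(m)
  # sample SD of (1,2,3) is exactly 1, so the column maps to (-1, 0, 1)
  expect_equal(unname(z$values[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z$values), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z$values, 2, stats::sd), c(a = 1, b = 1),
               tolerance = 1e-12)
  # idempotence
  z2 <- zscore_regions(z$values)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  m[, "b"] <- 5
  expect_error(zscore_regions(m), "zero-variance region\\(s\\): b")
  expect_error(zscore_regions(m[1:2, ]), "at least 3")
})

test_that("PCA of a rank-1 matrix concentrates all variance on PC1", {
  x <- cbind(r1 = c(-1, 0, 1, 2), r2 = c(-2, 0, 2, 4))
  z <- zscore_regions(x)$values
  fit <- fit_pca(z, K = 1)
  expect_equal(fit$variance_explained, 1)
  expect_equal(abs(unname(fit$loadings[, 1])), rep(1 / sqrt(2), 2))
})

test_that("fit_pca matches a brute-force covariance eigendecomposition", {
  set.seed(404)
  for (i in 1:10) {
    n <- sample(10:30, 1); p <- sample(4:8, 1)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("r", 1:p)))
    fit <- fit_pca(x, K = p, align = FALSE)
    ev <- eigen(stats::cov(x), symmetric = TRUE)
    expect_equal(fit$all_variance, ev$values / sum(ev$values),
                 tolerance = 1e-8)
    for (k in seq_len(p))
      expect_equal(abs(sum(fit$loadings[, k] * ev$vectors[, k])), 1,
                   tolerance = 1e-8)
  }
})

test_that("scores are the projection of the normalized data", {
  set.seed(11)
  x <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("r", 1:6)))
  z <- zscore_regions(x)$values
  fit <- fit_pca(z, K = 3)
  expect_equal(unname(fit$scores), unname(z %*% fit$loadings),
               tolerance = 1e-12)
  # unit-norm, mutually orthogonal loading columns
  g <- crossprod(fit$loadings)
  expect_equal(unname(g), diag(3), tolerance = 1e-8)
  # score variances proportional to eigenvalues, columns uncorrelated
  sc_cov <- stats::cov(fit$scores)
  expect_equal(unname(diag(sc_cov)) / sum(apply(z, 2, stats::var)),
               unname(fit$variance_explained), tolerance = 1e-8)
  expect_lt(max(abs(sc_cov[upper.tri(sc_cov)])), 1e-10)
  # planted rank-2 noiseless matrix: first two components carry everything
  b <- matrix(rnorm(12), 6, 2)
  y <- matrix(rnorm(40), 20, 2) %*% t(b)
  colnames(y) <- paste0("r", 1:6)
  fit2 <- fit_pca(scale(y, scale = FALSE), K = 2)
  expect_equal(sum(fit2$variance_explained), 1, tolerance = 1e-10)
  expect_error(fit_pca(z, K = 25), "K must be")
})

test_that("scree elbow selection lands after the dominant components", {
  expect_equal(select_k_scree(c(0.42, 0.08, 0.04, 0.03, 0.02, 0.01)), 2L)
  expect_equal(select_k_scree(c(0.9, 0.05, 0.05)), 2L)
  # gentle geometric decay has no elbow: floor with a warning
  flat <- 0.03 * 0.97^(0:49); flat <- flat / sum(flat)
  expect_warning(k <- select_k_scree(flat), "no clear elbow")
  expect_equal(k, 2L)
  expect_error(select_k_scree(c(0.6, 0.4)), "at least 3")
})

test_that("sign alignment is idempotent and reconstruction-invariant", {
  set.seed(21)
  x <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("r", 1:5)))
  z <- zscore_regions(x)$values
  fit <- fit_pca(z, K = 3, align = FALSE)
  recon <- fit$scores %*% t(fit$loadings)
  flipped <- fit
  flipped$loadings <- -flipped$loadings
  flipped$scores <- -flipped$scores
  a1 <- align_signs(flipped)
  a2 <- align_signs(align_signs(fit))
  expect_equal(a1$loadings, a2$loadings, tolerance = 1e-12)
  expect_equal(a1$scores %*% t(a1$loadings), recon, tolerance = 1e-12)
  expect_gt(mean(a1$loadings[, 1]), 0)
  # all-negative PC1 flips to all-positive
  neg <- fit; neg$loadings[, 1] <- -abs(neg$loadings[, 1])
  expect_true(all(align_signs(neg)$loadings[, 1] >= 0))
})

test_that("orient_to_reference fixes score signs without touching the fit", {
  set.seed(31)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("r", 1:6)))
  z <- zscore_regions(x)$values
  fit <- fit_pca(z, K = 2)
  ref <- -fit$loadings[, 2]   # anti-aligned reference
  recon <- fit$scores %*% t(fit$loadings)
  or <- orient_to_reference(fit, ref, components = 2)
  expect_gt(stats::cor(or$loadings[, 2], ref), 0)
  expect_equal(or$scores %*% t(or$loadings), recon, tolerance = 1e-12)
})

test_that("hemisphere PCA mirrors the whole-brain fit on symmetric data", {
  d <- make_dataset(n = 150, seed = 61, placement_fractions = c(1, 0, 0))
  whole <- pca_by_placement(d$dvol, d$cohort, K = 2)$RUL
  hemi <- hemisphere_pca(d$dvol, d$atlas, "right", K = 2, whole_brain = whole)
  expect_equal(nrow(hemi$loadings), 42L)
  expect_true(all(abs(hemi$comparison$r_loading) > 0.8))
  # zeroing one hemisphere makes its PCA degenerate
  broken <- unclass(d$dvol)
  broken[, d$atlas$name[d$atlas$hemisphere == "left"]] <- 0
  bm <- regional_matrix(broken, rownames(d$dvol), colnames(d$dvol),
                        "dvol_percent")
  expect_error(hemisphere_pca(bm, d$atlas, "left", K = 2), "zero-variance")
})

test_that("placement-stratified PCA never pools groups", {
  d <- make_dataset(n = 90, seed = 71, voxels_per_region = 20)
  fits <- pca_by_placement(d$dvol, d$cohort, K = 2)
  expect_setequal(names(fits), unique(d$cohort$placement))
  for (g in names(fits))
    expect_equal(nrow(fits[[g]]$scores), sum(d$cohort$placement == g))
})
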