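test_that("ols_fit reproduces exact fits and the normal-equations oracle", {
  # simple regression y = 1 + x
  f <- ols_fit(c(1, 2, 3), data.frame(x = c(0, 1, 2)))
  expect_equal(f$coefficients$beta, c(1, 1), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  # random data against explicit normal equations
  set.seed(7)
  for (i in 1:5) {
    n <- 40
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- rnorm(n)
    f <- ols_fit(y, X)
    Xm <- cbind(1, as.matrix(X))
    beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
    expect_equal(f$coefficients$beta, as.numeric(beta), tolerance = 1e-10)
    res <- y - Xm %*% beta
    s2 <- sum(res^2) / (n - 4)
    se <- sqrt(diag(solve(t(Xm) %*% Xm)) * s2)
    expect_equal(f$coefficients$se, unname(se), tolerance = 1e-10)
    expect_equal(f$coefficients$t, f$coefficients$beta / f$coefficients$se)
  }
  expect_error(ols_fit(rnorm(20), data.frame(a = 1:20, b = 2 * (1:20))),
               "dependent column\\(s\\): b")
})

test_that("BH step-up adjustment matches hand computation and a brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.7), 0.7)
  # order invariance
  p <- c(0.04, 0.001, 0.7, 0.02, 0.3)
  o <- sample(5)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  # independent step-up oracle: q_(i) = min over j >= i of p_(j) m / j
  bh_oracle <- function(p) {
    m <- length(p); ord <- order(p)
    q <- p[ord] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(ord)]
  }
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("effect sizes and rank correlations match hand values", {
  expect_equal(cohens_d_one_sample(c(1, 2, 3)), 2)     # mean 2, sample SD 1
  expect_equal(cohens_d_one_sample(c(-2, -1, 1, 2)), 0)
  expect_error(cohens_d_one_sample(rep(4, 5)), "zero")
  expect_error(cohens_d_one_sample(1), "at least 2")
  expect_equal(spearman_region_correlation(1:10, exp(1:10))$rho, 1)
  expect_equal(spearman_region_correlation(1:10, -(1:10)^3)$rho, -1)
  expect_equal(spearman_region_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_error(spearman_region_correlation(rep(1, 5), 1:5), "constant")
})

test_that("regional EF-volume regressions detect planted coupling", {
  d <- make_dataset(n = 150, seed = 81, truth = list(kappa = 0.08),
                    voxels_per_region = 20)
  tab <- region_ef_volume_regression(d$dvol, d$ef, d$cohort)
  expect_equal(nrow(tab), 85L)
  expect_identical(tab$region, d$atlas$name)
  expect_true(all(tab$p_fdr >= tab$p_raw))
  expect_gt(sum(tab$p_fdr < 0.05), 10)
  # without coupling, FDR controls discoveries
  d0 <- make_dataset(n = 150, seed = 82, truth = list(kappa = 0),
                     voxels_per_region = 20)
  tab0 <- region_ef_volume_regression(d0$dvol, d0$ef, d0$cohort)
  expect_lt(sum(tab0$p_fdr < 0.05), 5)
  # constant EF column is a rank error
  efc <- unclass(d$ef); efc[, 3] <- 2
  expect_error(region_ef_volume_regression(
    d$dvol, regional_matrix(efc, rownames(d$ef), colnames(d$ef), "ef_vpm"),
    d$cohort), "dependent")
})

test_that("outcome models assemble the requested designs", {
  d <- make_dataset(n = 200, seed = 91)
  pd <- lapply(pca_by_placement(d$dvol, d$cohort, K = 2),
               orient_to_reference, reference = d$truth$L2)
  pe <- pca_by_placement(d$ef, d$cohort, K = 2)
  for (m in c("dvol", "ef", "cross")) {
    fit <- outcome_model(d$cohort, pca_dvol = pd, pca_ef = pe, model = m)
    expect_s3_class(fit, "regression_result")
    expect_equal(fit$n, 200L)
    expect_setequal(setdiff(fit$coefficients$term, "(Intercept)"),
                    switch(m,
                           dvol = c("PC1_dVol", "PC2_dVol", "age", "nECT"),
                           ef = c("PC1_EF", "PC2_EF", "age", "nECT"),
                           cross = c("PC1_EF", "PC2_dVol", "age", "nECT")))
  }
  expect_true(length(attr(outcome_model(d$cohort, pca_dvol = pd,
                                        model = "dvol"), "per_group")) >= 1)
  # breaking the outcome link drives the PC coefficients toward zero
  scrambled <- d$cohort
  set.seed(92)
  scrambled$delta_madrs <- sample(scrambled$delta_madrs)
  f0 <- outcome_model(scrambled, pca_dvol = pd, model = "dvol")
  cf <- f0$coefficients
  expect_lt(abs(cf$t[cf$term == "PC2_dVol"]), 3.5)
})

test_that("site random-intercept sensitivity model degrades gracefully", {
  d <- make_dataset(n = 200, seed = 101, truth = list(site_sd = 0))
  pd <- lapply(pca_by_placement(d$dvol, d$cohort, K = 2),
               orient_to_reference, reference = d$truth$L2)
  scores <- data.frame(PC1_dVol = stack_scores_for_test(pd, d$cohort, 1),
                       PC2_dVol = stack_scores_for_test(pd, d$cohort, 2))
  mm <- mixed_model_site(d$cohort, scores)
  ols <- ols_fit(d$cohort$delta_madrs,
                 data.frame(scores, age = d$cohort$age, nECT = d$cohort$n_ect))
  b_mm <- mm$coefficients$beta[mm$coefficients$term == "PC2_dVol"]
  b_ols <- ols$coefficients$beta[ols$coefficients$term == "PC2_dVol"]
  # no planted site variance: fixed effect matches OLS closely, same sign
  expect_equal(b_mm, b_ols, tolerance = 0.05)
  expect_equal(sign(b_mm), sign(b_ols))
  # planted site intercepts are picked up by the random effect
  ds <- make_dataset(n = 200, seed = 102, truth = list(site_sd = 1.5))
  pds <- lapply(pca_by_placement(ds$dvol, ds$cohort, K = 2),
                orient_to_reference, reference = ds$truth$L2)
  ss <- data.frame(PC1_dVol = stack_scores_for_test(pds, ds$cohort, 1),
                   PC2_dVol = stack_scores_for_test(pds, ds$cohort, 2))
  # outcome noise unrelated to site here, so plant site into the outcome too
  site_eff <- stats::setNames(rnorm(length(unique(ds$cohort$site_id)), 0, 0.2),
                              unique(ds$cohort$site_id))
  ds$cohort$delta_madrs <- ds$cohort$delta_madrs +
    unname(site_eff[ds$cohort$site_id])
  mm2 <- mixed_model_site(ds$cohort, ss)
  expect_gt(mm2$site_sd, 0)
  one_site <- d$cohort
  one_site$site_id <- "site01"
  expect_error(mixed_model_site(one_site, scores), "ols_fit")
})
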