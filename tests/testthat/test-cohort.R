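test_that("cohort generation matches the stated demographic world", {
  cohort <- generate_cohort(386, seed = 1)
  expect_equal(nrow(cohort), 386L)
  expect_lt(abs(mean(cohort$age) - 54), 2)
  expect_true(all(cohort$age >= 18 & cohort$age <= 90))
  expect_true(all(cohort$madrs_pre >= 10))
  expect_true(all(cohort$madrs_pre == round(cohort$madrs_pre)))
  expect_true(all(cohort$n_ect >= 2))
  # placement consistency invariants
  expect_true(all(cohort$n_ect_bt[cohort$placement == "RUL"] == 0))
  expect_true(all(cohort$n_ect_rul[cohort$placement == "BT"] == 0))
  mix <- cohort[cohort$placement == "MIX", ]
  expect_true(all(mix$n_ect_rul > 0 & mix$n_ect_bt > 0))
  expect_equal(cohort$n_ect, cohort$n_ect_rul + cohort$n_ect_bt)
  # session counts per placement near their generating means
  expect_lt(abs(mean(cohort$n_ect[cohort$placement == "RUL"]) - 10.9), 1.5)
  expect_lt(abs(mean(cohort$n_ect[cohort$placement == "BT"]) - 14.3), 2.5)
})

test_that("cohort generation is deterministic and validates inputs", {
  expect_identical(generate_cohort(50, seed = 3), generate_cohort(50, seed = 3))
  expect_false(identical(generate_cohort(50, seed = 3),
                         generate_cohort(50, seed = 4)))
  rul_only <- generate_cohort(100, c(1, 0, 0), 5, seed = 2)
  expect_true(all(rul_only$placement == "RUL"))
  expect_true(all(rul_only$n_ect_bt == 0))
  expect_error(generate_cohort(1), "n >= 2")
  expect_error(generate_cohort(10, c(0.5, 0.5, 0.5)), "sum")
})

test_that("cdn_like reference map has the expected sign and symmetry structure", {
  atlas <- build_atlas()
  ref <- generate_reference_map(atlas, "cdn_like", seed = 5)
  v <- ref$values
  expect_lt(v[["hippocampus_lh"]], 0)
  expect_lt(v[["amygdala_rh"]], 0)
  expect_lt(v[["medialorbitofrontal_lh"]], 0)
  expect_lt(v[["rostralanteriorcingulate_rh"]], 0)
  expect_gt(v[["superiorparietal_rh"]], 0)
  expect_gt(v[["inferiorparietal_lh"]], 0)
  expect_gt(v[["lateraloccipital_rh"]], 0)
  pairs <- homolog_pairs(atlas)
  expect_equal(unname(v[pairs$left]), unname(v[pairs$right]))
  expect_equal(sum(v^2), 1)
  expect_error(generate_reference_map(atlas, "lesion"), "arg")
})

test_that("random_smooth maps differ by seed, stay symmetric and unit norm", {
  atlas <- build_atlas()
  r1 <- generate_reference_map(atlas, "random_smooth", seed = 1)
  r2 <- generate_reference_map(atlas, "random_smooth", seed = 2)
  expect_false(identical(r1$values, r2$values))
  for (r in list(r1, r2)) {
    expect_equal(sum(r$values^2), 1)
    pairs <- homolog_pairs(atlas)
    expect_equal(unname(r$values[pairs$left]), unname(r$values[pairs$right]))
  }
})

test_that("planted volumetric model honours its degenerate limits", {
  atlas <- build_atlas()
  cohort <- generate_cohort(30, seed = 7)
  ref <- generate_reference_map(atlas, "cdn_like", seed = 8)
  ef <- build_ef_matrix(cohort, atlas, voxels_per_region = 20, seed = 9)
  # noise 0, kappa 0, no second factor: rank-1 change matrix
  gen <- generate_outcomes_and_volumes(
    cohort, atlas, ref, ef,
    list(noise_sd = 0, kappa = 0, b_scale = 0), seed = 10)
  expect_equal(qr(unclass(gen$dvol))$rank, 1L)
  expect_true(all(gen$truth$L1 > 0))
  expect_equal(sum(gen$truth$L2^2), 1)
  expect_equal(stats::cor(gen$truth$L2, ref$values), 1)
  # misaligned EF errors
  expect_error(generate_outcomes_and_volumes(cohort[1:10, ], atlas, ref, ef),
               "aligned")
})

test_that("outcomes carry the planted confounds and MADRS accounting", {
  d <- make_dataset(n = 250, seed = 21)
  cohort <- d$cohort
  expect_true(all(cohort$madrs_post >= 0))
  expect_equal(cohort$delta_madrs,
               (cohort$madrs_post - cohort$madrs_pre) / cohort$madrs_pre)
  expect_gt(stats::cor(cohort$n_ect, cohort$delta_madrs), 0)
  expect_lt(stats::cor(cohort$age, cohort$delta_madrs), 0)
})

test_that("a null planted effect leaves no adjusted b-outcome correlation", {
  d <- make_dataset(n = 300, seed = 31, truth = list(beta_outcome = 0))
  fit <- ols_fit(d$cohort$delta_madrs,
                 data.frame(b = d$truth$b, age = d$cohort$age,
                            nECT = d$cohort$n_ect))
  cf <- fit$coefficients
  expect_lt(abs(cf$t[cf$term == "b"]), 3)
})

test_that("baseline volumes invert the change matrix exactly", {
  d <- make_dataset(n = 25, seed = 41, voxels_per_region = 20)
  expect_true(all(d$v1 > 0) && all(d$v2 > 0))
  back <- volume_change_percent(d$v1, d$v2)
  expect_equal(unclass(back), unclass(d$dvol), tolerance = 1e-12)
  # a 6.7% change corresponds to a volume ratio of 1.067
  dv <- unclass(d$dvol)
  dv[3, 7] <- 6.7
  dvol2 <- regional_matrix(dv, rownames(d$dvol), colnames(d$dvol),
                           "dvol_percent")
  vols <- generate_baseline_volumes(d$atlas, dvol2, seed = 42)
  expect_equal(unclass(vols$v2)[3, 7] / unclass(vols$v1)[3, 7], 1.067)
  # zero change reproduces the baseline
  dv0 <- regional_matrix(matrix(0, 25, 85), rownames(d$dvol),
                         colnames(d$dvol), "dvol_percent")
  v0 <- generate_baseline_volumes(d$atlas, dv0, seed = 43)
  expect_equal(unclass(v0$v2), unclass(v0$v1))
  dv[1, 1] <- -100
  expect_error(generate_baseline_volumes(
    d$atlas, regional_matrix(dv, rownames(d$dvol), colnames(d$dvol),
                             "dvol_percent"), seed = 44), "-100")
})

test_that("generation is reproducible end to end given a seed", {
  d1 <- make_dataset(n = 20, seed = 99, voxels_per_region = 20)
  d2 <- make_dataset(n = 20, seed = 99, voxels_per_region = 20)
  expect_identical(d1$cohort, d2$cohort)
  expect_identical(unclass(d1$ef), unclass(d2$ef))
  expect_identical(unclass(d1$dvol), unclass(d2$dvol))
  expect_identical(unclass(d1$v1), unclass(d2$v1))
})
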