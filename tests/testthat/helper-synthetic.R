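# Shared fixture builder: a fully generated synthetic dataset.  Unit tests
# use fewer voxels per region than the default to stay fast; regional
# trimmed means are stable well below the default count.
make_dataset <- function(n = 120, seed = 1, truth = list(),
                         reference_mode = "cdn_like",
                         placement_fractions = c(246, 79, 61) / 386,
                         voxels_per_region = 30) {
  atlas <- build_atlas()
  cohort <- generate_cohort(n, placement_fractions, n_sites = 6, seed = seed)
  reference <- generate_reference_map(atlas, reference_mode, seed = seed + 1)
  ef <- build_ef_matrix(cohort, atlas, voxels_per_region = voxels_per_region,
                        seed = seed + 2)
  gen <- generate_outcomes_and_volumes(cohort, atlas, reference, ef,
                                       truth, seed = seed + 3)
  vols <- generate_baseline_volumes(atlas, gen$dvol, seed = seed + 4)
  list(atlas = atlas, cohort = gen$cohort, reference = reference, ef = ef,
       dvol = gen$dvol, truth = gen$truth, v1 = vols$v1, v2 = vols$v2)
}

# stack per-placement PCA scores into cohort order (mirrors the internal
# assembly used by outcome_model)
stack_scores_for_test <- function(pca_list, cohort, component) {
  out <- rep(NA_real_, nrow(cohort))
  for (g in names(pca_list)) {
    sc <- pca_list[[g]]$scores
    idx <- match(rownames(sc), cohort$subject_id)
    out[idx] <- sc[, component]
  }
  out
}

# one-row cohort slice with chosen fields, for EF surrogate unit tests
make_subject <- function(age = 54, placement = "RUL") {
  cohort <- generate_cohort(2, seed = 1)
  cohort$age[1] <- age
  cohort$placement[1] <- placement
  cohort[1, ]
}
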