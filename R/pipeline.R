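# End-to-end orchestration: simulate -> EF -> stratified PCA per measure ->
# similarity -> outcome models -> regional statistics -> laterality.
# Every random draw derives from the single master seed in the config, so
# a rerun with the same config reproduces every output.

#' Default pipeline configuration
#'
#' A nested list mirroring the stages: `seed`; `cohort` (n,
#' placement_fractions, n_sites); `truth` (planted generator constants,
#' see [default_truth_params()]); `ef` (an [ef_config()] plus
#' voxels_per_region); `analysis` (K, n_perm, alpha, reference mode,
#' hemisphere switch).
#'
#' @param seed Master seed.
#' @param n Cohort size.
#' @param n_perm Permutations for the similarity null (0 skips the stage).
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 1, n = 386, n_perm = 199) {
  structure(list(
    seed = seed,
    cohort = list(n = n, placement_fractions = c(246, 79, 61) / 386,
                  n_sites = 10),
    truth = default_truth_params(),
    ef = list(config = ef_config(), voxels_per_region = 60),
    analysis = list(K = 2, n_perm = n_perm, alpha = 0.05,
                    reference_mode = "cdn_like", hemispheres = TRUE)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the defaults of
#' [default_config()]; the `seed` field is mandatory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package; use JSON")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$seed)) stop("config must set a seed")
  cfg <- utils::modifyList(unclass(default_config(seed = raw$seed)), raw)
  cfg$ef$config <- do.call(ef_config, utils::modifyList(
    list(), cfg$ef$config[setdiff(names(cfg$ef$config), "electrode_positions")]))
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(quiet, stage, detail) {
  if (!quiet) message(sprintf("[%s] %s", stage, detail))
}

reg_table <- function(fit) {
  cf <- fit$coefficients
  list(terms = cf$term, beta = cf$beta, se = cf$se, t = cf$t, p = cf$p,
       n = fit$n, r_squared = fit$r_squared, label = fit$model_label,
       p_method = "parametric t")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a cohort, a reference map, the EF dose matrix and the planted
#' volume changes; fits the six placement-stratified PCAs (three placement
#' groups x two measures); tests loading-reference similarity against the
#' baseline-reshuffling null; fits the confounder-adjusted outcome models
#' (volume, EF and cross designs); computes the region-wise EF-to-volume
#' table; and repeats the volumetric PCA per hemisphere.  Returns a report
#' list and, when `out_dir` is given, writes subjects.csv, dvol.csv,
#' ef.csv, v1.csv, v2.csv, reference_map.csv, atlas.csv and report.json
#' there.
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @param out_dir Optional output directory (created if missing).
#' @param quiet Suppress per-stage log lines.
#' @return The report list, invisibly when `out_dir` is given, otherwise
#'   visibly.
#' @export
run_full <- function(config = default_config(), out_dir = NULL,
                     quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  seed <- config$seed
  t0 <- proc.time()[3]
  tick <- function(stage, detail) {
    stage_log(quiet, stage, sprintf("%s (%.1f s)", detail,
                                    proc.time()[3] - t0))
  }

  atlas <- build_atlas()
  tick("atlas", sprintf("%d regions", nrow(atlas)))

  cohort <- generate_cohort(config$cohort$n,
                            config$cohort$placement_fractions,
                            config$cohort$n_sites, seed = seed)
  tick("cohort", sprintf("%d subjects", nrow(cohort)))

  reference <- generate_reference_map(atlas, config$analysis$reference_mode,
                                      seed = seed + 1)
  ef <- build_ef_matrix(cohort, atlas, config$ef$config,
                        config$ef$voxels_per_region, seed = seed + 2)
  tick("efield", sprintf("%d x %d EF matrix", nrow(ef), ncol(ef)))

  gen <- generate_outcomes_and_volumes(cohort, atlas, reference, ef,
                                       config$truth, seed = seed + 3)
  cohort <- gen$cohort; dvol <- gen$dvol
  vols <- generate_baseline_volumes(atlas, dvol, seed = seed + 4)
  tick("volumes", "volume change and baseline/follow-up volumes")

  K <- config$analysis$K
  pca_dvol <- pca_by_placement(dvol, cohort, K = K)
  pca_ef <- pca_by_placement(ef, cohort, K = K)
  tick("pca", sprintf("%d PCA blocks",
                      length(pca_dvol) + length(pca_ef)))

  similarity <- NULL
  if (config$analysis$n_perm > 0) {
    similarity <- baseline_shuffle_null(vols$v1, vols$v2, reference,
                                        cohort$placement, K = K,
                                        n_perm = config$analysis$n_perm,
                                        seed = seed + 5)
    tick("similarity", sprintf("%d permutations per group",
                               config$analysis$n_perm))
  } else stage_log(quiet, "similarity", "skipped (n_perm = 0)")

  fits <- list(dvol = outcome_model(cohort, pca_dvol = pca_dvol,
                                    model = "dvol"),
               ef = outcome_model(cohort, pca_ef = pca_ef, model = "ef"),
               cross = outcome_model(cohort, pca_dvol = pca_dvol,
                                     pca_ef = pca_ef, model = "cross"))
  tick("outcome", "pooled outcome regressions (dvol, ef, cross)")

  region_table <- region_ef_volume_regression(dvol, ef, cohort)
  tick("regional", "85 EF~volume regressions with FDR")

  laterality <- NULL
  if (isTRUE(config$analysis$hemispheres)) {
    laterality <- lapply(stats::setNames(nm = names(pca_dvol)), function(g) {
      idx <- cohort$placement == g
      sub <- regional_matrix(unclass(dvol)[idx, , drop = FALSE],
                             cohort$subject_id[idx], atlas$name,
                             "dvol_percent")
      lapply(stats::setNames(nm = c("left", "right")), function(side)
        hemisphere_pca(sub, atlas, side, K = K,
                       whole_brain = pca_dvol[[g]],
                       group_label = paste0(g, "_", side)))
    })
    tick("laterality", "hemisphere-split PCAs")
  }

  report <- list(
    package_version = as.character(utils::packageVersion("ectnet")),
    seed = seed,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    n_subjects = nrow(cohort),
    placements = as.list(table(cohort$placement)),
    pca = lapply(c(pca_dvol, stats::setNames(pca_ef,
                                             paste0(names(pca_ef), "_ef"))),
                 function(p) list(group = p$group_label,
                                  variance_explained = p$variance_explained)),
    similarity = if (!is.null(similarity)) lapply(similarity, function(s)
      list(group = s$group, r_obs = as.list(s$r_obs),
           p_perm = s$p_perm, p_per_component = as.list(s$p_per_component),
           n_perm = s$n_perm, n_regions = s$n_regions,
           statistic = s$statistic_def,
           p_method = "permutation (baseline reshuffle)"))
      else "skipped (n_perm = 0)",
    outcome_models = lapply(fits, reg_table),
    region_table = region_table,
    laterality = if (!is.null(laterality)) lapply(laterality, function(g)
      lapply(g, function(h) list(group = h$group_label,
                                 variance_explained = h$variance_explained,
                                 comparison = h$comparison)))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(cohort),
                     file.path(out_dir, "subjects.csv"), row.names = FALSE)
    write_regional_csv(dvol, file.path(out_dir, "dvol.csv"))
    write_regional_csv(ef, file.path(out_dir, "ef.csv"))
    write_regional_csv(vols$v1, file.path(out_dir, "v1.csv"))
    write_regional_csv(vols$v2, file.path(out_dir, "v2.csv"))
    utils::write.csv(data.frame(region = atlas$name,
                                value = unname(reference$values)),
                     file.path(out_dir, "reference_map.csv"),
                     row.names = FALSE)
    write_atlas_csv(atlas, file.path(out_dir, "atlas.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         force = TRUE)
    tick("report", paste("written to", out_dir))
    return(invisible(c(report, list(
      cohort = cohort, dvol = dvol, ef = ef, v1 = vols$v1, v2 = vols$v2,
      reference = reference, truth = gen$truth,
      pca_dvol = pca_dvol, pca_ef = pca_ef,
      similarity_full = similarity, fits = fits))))
  }
  c(report, list(cohort = cohort, dvol = dvol, ef = ef,
                 v1 = vols$v1, v2 = vols$v2,
                 reference = reference, truth = gen$truth,
                 pca_dvol = pca_dvol, pca_ef = pca_ef,
                 similarity_full = similarity, fits = fits))
}
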