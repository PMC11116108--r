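# Surrogate electric-field dose model.  A two-electrode exponential-decay
# field stands in for a finite-element solve: it preserves the three
# properties the downstream analysis needs (placement asymmetry, bitemporal
# > unilateral magnitude, age attenuation) and nothing else.  It is NOT a
# realistic field solver.

#' Electric-field surrogate configuration
#'
#' @param electrode_positions Named list mapping placement to a 2x3 matrix
#'   of electrode coordinates in the atlas frame (mm).  Defaults place a
#'   C2-like vertex electrode and an FT8-like right fronto-temporal
#'   electrode for RUL, and FT8-/FT9-like bilateral fronto-temporal
#'   electrodes for BT.
#' @param decay_length Exponential decay length of the field (mm).
#' @param base_amplitude Field scale, V/m per ampere of electrode current.
#' @param age_attenuation Fractional field decrease per year of age above
#'   the reference age of 54 (brain atrophy increases the CSF gap); the
#'   multiplier is floored at 0.2.  Must lie in \[0, 0.05).
#' @param anatomy_sd SD of the per-subject log-normal anatomical gain
#'   (head size, CSF and fat differences); set 0 for a purely geometric
#'   field.
#' @param voxel_jitter_sd SD of the isotropic voxel scatter around each
#'   region centroid (mm).
#' @param device_current Named current per device, mA.
#' @param trim_fraction Fraction trimmed from each tail when averaging
#'   voxels within a region; in \[0, 0.5).
#' @return An `ef_config` list.
#' @export
ef_config <- function(electrode_positions = list(
                        RUL = rbind(c2 = c(20, -15, 110),
                                    ft8 = c(68, 5, -10)),
                        BT = rbind(ft8 = c(68, 5, -10),
                                   ft9 = c(-68, 5, -10))),
                      decay_length = 45,
                      base_amplitude = 200,
                      age_attenuation = 0.005,
                      anatomy_sd = 0.15,
                      voxel_jitter_sd = 6,
                      device_current = c(Thymatron = 900, spECTrum = 800),
                      trim_fraction = 0.01) {
  stopifnot(decay_length > 0,
            age_attenuation >= 0, age_attenuation < 0.05,
            trim_fraction >= 0, trim_fraction < 0.5,
            all(c("RUL", "BT") %in% names(electrode_positions)))
  structure(list(electrode_positions = electrode_positions,
                 decay_length = decay_length,
                 base_amplitude = base_amplitude,
                 age_attenuation = age_attenuation,
                 anatomy_sd = anatomy_sd,
                 voxel_jitter_sd = voxel_jitter_sd,
                 device_current = device_current,
                 trim_fraction = trim_fraction),
            class = "ef_config")
}

#' Simulate per-region voxel field values for one subject
#'
#' Voxel positions are jittered isotropically around each region centroid;
#' the unit-current field at a voxel is
#' `base_amplitude * sum_e exp(-d_e / decay_length)` over the placement's
#' two electrodes, multiplied by the age factor
#' `max(1 - age_attenuation * (age - 54), 0.2)` and a per-subject
#' log-normal anatomical gain.  Values are in V/m per ampere; device
#' scaling is applied later by [scale_to_device()].
#'
#' @param atlas A `region_atlas`.
#' @param subject One-row `ect_cohort` slice (uses `age`).
#' @param config An [ef_config()].
#' @param placement `"RUL"` or `"BT"` (a MIX course is simulated as both
#'   and combined with [mix_ef()]).
#' @param voxels_per_region Voxels drawn per region (>= 10).
#' @param seed Integer seed; the same seed yields the same anatomy gain
#'   and voxel scatter for both placements of one subject.
#' @return Named list (atlas order) of numeric voxel-value vectors.
#' @export
simulate_voxel_ef <- function(atlas, subject, config = ef_config(),
                              placement = subject$placement,
                              voxels_per_region = 60, seed = 1) {
  stopifnot(inherits(atlas, "region_atlas"), voxels_per_region >= 10)
  if (!placement %in% names(config$electrode_positions))
    stop("unknown placement: ", placement)
  elec <- config$electrode_positions[[placement]]
  R <- nrow(atlas); V <- voxels_per_region
  with_seed(seed, {
    gain <- exp(stats::rnorm(1, 0, config$anatomy_sd))
    jit <- matrix(stats::rnorm(R * V * 3, 0, config$voxel_jitter_sd), R * V, 3)
    cent <- as.matrix(atlas[, c("x", "y", "z")])
    pos <- cent[rep(seq_len(R), each = V), , drop = FALSE] + jit
    field <- 0
    for (e in seq_len(nrow(elec))) {
      d <- sqrt(rowSums((pos - matrix(elec[e, ], nrow(pos), 3, byrow = TRUE))^2))
      field <- field + exp(-d / config$decay_length)
    }
    agef <- max(1 - config$age_attenuation * (subject$age - 54), 0.2)
    vals <- config$base_amplitude * field * agef * gain
    split(vals, factor(rep(atlas$name, each = V), levels = atlas$name))
  })
}

#' Percentile-trimmed mean of voxel values within a region
#'
#' Removes the `k = ceiling(trim_fraction * n)` smallest and `k` largest
#' values by count (a boundary-effect guard), then averages the rest.  The
#' count-based rule is unambiguous for any `n` and reduces to the plain
#' mean of the central values.
#'
#' @param voxel_values Numeric vector, length >= 3.
#' @param trim_fraction Fraction per tail, default 0.01.
#' @return The trimmed mean (scalar).
#' @export
trimmed_roi_mean <- function(voxel_values, trim_fraction = 0.01) {
  n <- length(voxel_values)
  if (n < 3) stop("need at least 3 voxel values")
  k <- ceiling(trim_fraction * n)
  if (n <= 2 * k) stop("trimming removes all values (n = ", n, ", k = ", k, ")")
  s <- sort(voxel_values)
  mean(s[(k + 1):(n - k)])
}

#' Scale a unit-current field matrix to device current
#'
#' Each subject's row is multiplied by the current of their device in
#' amperes (Thymatron 0.9 A, spECTrum 0.8 A by default).
#'
#' @param unit_field A `regional_matrix` in V/m per ampere.
#' @param device Character vector of device names, one per subject.
#' @param device_current Named currents in mA.
#' @return A `regional_matrix` in V/m (`measure = "ef_vpm"`).
#' @export
scale_to_device <- function(unit_field, device,
                            device_current = c(Thymatron = 900, spECTrum = 800)) {
  unknown <- setdiff(unique(device), names(device_current))
  if (length(unknown))
    stop("unknown device: ", paste(unknown, collapse = ", "))
  amps <- unname(device_current[device]) / 1000
  regional_matrix(unclass(unit_field) * amps, rownames(unit_field),
                  colnames(unit_field), "ef_vpm")
}

#' Session-weighted mixing of RUL and BT field vectors
#'
#' For a course switched from right-unilateral to bitemporal stimulation,
#' the effective regional field is the session-count-weighted mean
#' `w * ef_rul + (1 - w) * ef_bt` with `w = n_rul / (n_rul + n_bt)`,
#' elementwise.  E.g. 6 RUL + 18 BT sessions give `0.25 EF_RUL + 0.75 EF_BT`.
#'
#' @param ef_rul,ef_bt Aligned regional field vectors.
#' @param n_rul,n_bt Session counts (non-negative, sum >= 1).
#' @return The mixed field vector.
#' @export
mix_ef <- function(ef_rul, ef_bt, n_rul, n_bt) {
  if (n_rul < 0 || n_bt < 0) stop("session counts must be non-negative")
  if (n_rul + n_bt < 1) stop("need at least one session")
  if (length(ef_rul) != length(ef_bt)) stop("field vectors are not aligned")
  w <- n_rul / (n_rul + n_bt)
  w * ef_rul + (1 - w) * ef_bt
}

#' Build the subjects-by-regions EF matrix for a cohort
#'
#' Per subject: simulate the voxel field for the relevant placement(s),
#' trim-average within each region, scale to the device current, and for
#' MIX subjects combine the RUL and BT fields by session-count weighting.
#'
#' @param cohort An `ect_cohort`.
#' @param atlas A `region_atlas`.
#' @param config An [ef_config()].
#' @param voxels_per_region Voxels per region (default 60).
#' @param seed Integer master seed; subject i uses `seed + i`.
#' @return A `regional_matrix` (`ef_vpm`) aligned to the cohort.
#' @export
build_ef_matrix <- function(cohort, atlas, config = ef_config(),
                            voxels_per_region = 60, seed = 1) {
  stopifnot(inherits(cohort, "ect_cohort"), nrow(cohort) >= 1)
  n <- nrow(cohort); R <- nrow(atlas)
  unit <- matrix(NA_real_, n, R)
  trim1 <- function(vox) vapply(vox, trimmed_roi_mean, numeric(1),
                                trim_fraction = config$trim_fraction)
  for (i in seq_len(n)) {
    s <- cohort[i, ]
    si <- seed + i
    if (s$placement == "RUL") {
      unit[i, ] <- trim1(simulate_voxel_ef(atlas, s, config, "RUL",
                                           voxels_per_region, si))
    } else if (s$placement == "BT") {
      unit[i, ] <- trim1(simulate_voxel_ef(atlas, s, config, "BT",
                                           voxels_per_region, si))
    } else if (s$placement == "MIX") {
      r <- trim1(simulate_voxel_ef(atlas, s, config, "RUL",
                                   voxels_per_region, si))
      b <- trim1(simulate_voxel_ef(atlas, s, config, "BT",
                                   voxels_per_region, si))
      unit[i, ] <- mix_ef(r, b, s$n_ect_rul, s$n_ect_bt)
    } else stop("unknown placement: ", s$placement)
  }
  unit <- regional_matrix(unit, cohort$subject_id, atlas$name, "ef_vpm")
  scale_to_device(unit, cohort$device, config$device_current)
}
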