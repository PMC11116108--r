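# Confounder-adjusted outcome models and mass-univariate regional
# statistics.  Age and the number of ECT sessions enter every model:
# older patients respond better while carrying lower EF, and longer
# courses accompany both larger volume change and poorer outcome in
# observational samples, so omitting either invites spurious effects.

#' Ordinary least squares with a coefficient table
#'
#' Fits `y ~ 1 + design` and returns estimates, standard errors from the
#' residual variance, and two-sided t-test p-values on `n - p` degrees of
#' freedom.  Rank deficiency is an error naming the dependent columns.
#'
#' @param y Numeric response vector.
#' @param design Data frame (or matrix) of named predictor columns; an
#'   intercept is added.
#' @param model_label Label stored with the result.
#' @return A `regression_result`: `coefficients` data frame (`term`,
#'   `beta`, `se`, `t`, `p`), `n`, `df_residual`, `r_squared`,
#'   `model_label`.
#' @export
ols_fit <- function(y, design, model_label = "ols") {
  design <- as.data.frame(design)
  n <- length(y)
  if (nrow(design) != n) stop("y and design have different lengths")
  if (n <= ncol(design) + 1) stop("need n > number of coefficients")
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- n - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * s2)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = data.frame(term = colnames(X), beta = unname(beta),
                              se = unname(se), t = unname(tval),
                              p = unname(p), stringsAsFactors = FALSE),
    n = n, df_residual = df,
    r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    model_label = model_label), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Linear model [%s]: n = %d, R2 = %.3f\n",
              x$model_label, x$n, x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

# per-subject scores from a per-placement list of pca_result objects
stack_scores <- function(pca_list, cohort, component) {
  if (inherits(pca_list, "pca_result"))
    return(pca_list$scores[cohort$subject_id, component])
  out <- rep(NA_real_, nrow(cohort))
  for (g in names(pca_list)) {
    sc <- pca_list[[g]]$scores
    idx <- match(rownames(sc), cohort$subject_id)
    out[idx[!is.na(idx)]] <- sc[!is.na(idx), component]
  }
  if (anyNA(out)) stop("scores missing for some subjects")
  out
}

#' Confounder-adjusted clinical-outcome regression
#'
#' Regresses fractional MADRS change on principal-component scores plus
#' the two mandatory confounders (age, number of sessions).  Three designs:
#' `"dvol"` uses PC1 and PC2 of volume change; `"ef"` uses PC1 and PC2 of
#' the electric field; `"cross"` pits overall EF dose against the
#' network-like volume pattern (PC1_EF + PC2_dVol).  Scores come from
#' placement-stratified PCAs and are stacked across groups; the pooled
#' model is fitted over all subjects (per-group fits are attached for
#' groups with enough subjects).
#'
#' @param cohort An `ect_cohort` with outcomes filled.
#' @param pca_dvol,pca_ef Per-placement lists of `pca_result` (from
#'   [pca_by_placement()]) or single `pca_result` objects; only the
#'   measures a design needs must be supplied.
#' @param model `"dvol"`, `"ef"` or `"cross"`.
#' @return A `regression_result` for the pooled model, with a `per_group`
#'   attribute holding per-placement fits.
#' @export
outcome_model <- function(cohort, pca_dvol = NULL, pca_ef = NULL,
                          model = c("dvol", "ef", "cross")) {
  model <- match.arg(model)
  if (anyNA(cohort$delta_madrs)) stop("cohort outcomes are not filled")
  design <- switch(model,
    dvol = data.frame(
      PC1_dVol = stack_scores(pca_dvol, cohort, 1),
      PC2_dVol = stack_scores(pca_dvol, cohort, 2)),
    ef = data.frame(
      PC1_EF = stack_scores(pca_ef, cohort, 1),
      PC2_EF = stack_scores(pca_ef, cohort, 2)),
    cross = data.frame(
      PC1_EF = stack_scores(pca_ef, cohort, 1),
      PC2_dVol = stack_scores(pca_dvol, cohort, 2)))
  design$age <- cohort$age
  design$nECT <- cohort$n_ect
  pooled <- ols_fit(cohort$delta_madrs, design,
                    model_label = paste0("outcome_", model, "_pooled"))
  per_group <- list()
  for (g in unique(cohort$placement)) {
    idx <- cohort$placement == g
    if (sum(idx) > ncol(design) + 2) {
      per_group[[g]] <- tryCatch(
        ols_fit(cohort$delta_madrs[idx], design[idx, , drop = FALSE],
                model_label = paste0("outcome_", model, "_", g)),
        error = function(e) NULL)
    }
  }
  attr(pooled, "per_group") <- per_group
  pooled
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), invariant to input
#' order up to reordering.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-sample Cohen's d
#'
#' `mean(x) / sd(x)` with the sample (n - 1) standard deviation; the
#' standardized magnitude of a regional volume change across subjects.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Cohen's d (scalar).
#' @export
cohens_d_one_sample <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation")
  mean(values) / s
}

#' Region-wise EF-to-volume-change regressions with FDR
#'
#' For every region r fits `dVol_r ~ EF_r + age + nECT` across subjects,
#' collects the EF t-statistic and p-value, applies Benjamini-Hochberg
#' correction across all 85 regional tests, and adds the one-sample
#' Cohen's d of the volume change plus region means.
#'
#' @param dvol,ef Aligned `regional_matrix` objects (% change, V/m).
#' @param cohort The matching `ect_cohort`.
#' @return A `region_stat_table` data frame (one row per region, atlas
#'   order): `region`, `t_ef`, `p_raw`, `p_fdr`, `cohens_d`, `mean_ef`,
#'   `mean_dvol`.
#' @export
region_ef_volume_regression <- function(dvol, ef, cohort) {
  stopifnot(identical(colnames(dvol), colnames(ef)),
            identical(rownames(dvol), rownames(ef)),
            identical(rownames(dvol), cohort$subject_id))
  regions <- colnames(dvol)
  t_ef <- p_raw <- d <- numeric(length(regions))
  for (j in seq_along(regions)) {
    fit <- ols_fit(unclass(dvol)[, j],
                   data.frame(EF = unclass(ef)[, j],
                              age = cohort$age, nECT = cohort$n_ect),
                   model_label = regions[j])
    row <- fit$coefficients[fit$coefficients$term == "EF", ]
    t_ef[j] <- row$t; p_raw[j] <- row$p
    d[j] <- cohens_d_one_sample(unclass(dvol)[, j])
  }
  out <- data.frame(region = regions, t_ef = t_ef, p_raw = p_raw,
                    p_fdr = bh_fdr(p_raw), cohens_d = d,
                    mean_ef = colMeans(unclass(ef)),
                    mean_dvol = colMeans(unclass(dvol)),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("region_stat_table", "data.frame")
  out
}

#' Spearman correlation across regions
#'
#' Rank correlation between per-region summaries (e.g. group-mean EF
#' against the regional volume-change effect size), with a p-value from
#' the t approximation on n - 2 degrees of freedom (approximate; exact
#' permutation inference is not attempted here).
#'
#' @param x,y Aligned numeric vectors without missing values.
#' @return List with `rho`, `p` and `n`.
#' @export
spearman_region_correlation <- function(x, y) {
  if (anyNA(x) || anyNA(y)) stop("missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  n <- length(x)
  rho <- stats::cor(x, y, method = "spearman")
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), n - 2), n = n,
       method = "t approximation")
}

#' Sensitivity analysis: site as a random effect
#'
#' Refits the outcome model as a linear mixed model with a random site
#' intercept (REML via lme4) and sex plus electrode placement as extra
#' fixed effects, to check that the pooled OLS conclusions are not driven
#' by site differences.  Fixed-effect p-values use the normal
#' approximation to the t statistic and are labeled approximate.
#'
#' @param cohort An `ect_cohort` with >= 3 sites and outcomes filled.
#' @param scores Data frame of named per-subject score columns (e.g.
#'   `PC1_dVol`, `PC2_dVol`).
#' @param fixed_extras Extra fixed effects among `"sex"`, `"placement"`.
#' @return A `regression_result` (fixed effects) with `site_sd` and
#'   `residual_sd` fields; `model_label = "mixed_site_sensitivity"`.
#' @export
mixed_model_site <- function(cohort, scores,
                             fixed_extras = c("sex", "placement")) {
  n_sites <- length(unique(cohort$site_id))
  if (n_sites < 3)
    stop("need >= 3 sites for a site random effect; use ols_fit instead")
  dat <- data.frame(delta_madrs = cohort$delta_madrs, scores,
                    age = cohort$age, nECT = cohort$n_ect,
                    sex = cohort$sex, placement = cohort$placement,
                    site_id = cohort$site_id, check.names = FALSE)
  extras <- intersect(fixed_extras, c("sex", "placement"))
  extras <- extras[vapply(extras, function(v)
    length(unique(dat[[v]])) > 1, logical(1))]
  form <- stats::as.formula(paste(
    "delta_madrs ~", paste(c(names(scores), "age", "nECT", extras),
                           collapse = " + "), "+ (1 | site_id)"))
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  cf <- as.data.frame(stats::coef(summary(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- structure(list(
    coefficients = data.frame(term = rownames(cf), beta = cf[, "Estimate"],
                              se = cf[, "Std. Error"], t = cf[, "t value"],
                              p = 2 * stats::pnorm(-abs(cf[, "t value"])),
                              stringsAsFactors = FALSE),
    n = nrow(dat), df_residual = NA_integer_, r_squared = NA_real_,
    model_label = "mixed_site_sensitivity"), class = "regression_result")
  out$site_sd <- vc$sdcor[vc$grp == "site_id"]
  out$residual_sd <- vc$sdcor[vc$grp == "Residual"]
  out$p_method <- "normal approximation to t (sensitivity analysis)"
  out
}
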