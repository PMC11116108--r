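# Normalization-then-PCA of regional matrices.  PCA is computed by SVD of
# the centered matrix (numerically equivalent to an eigendecomposition of
# the sample covariance); eigenvector sign is fixed by an explicit rule so
# results are reproducible across platforms.

#' Z-score each region across subjects
#'
#' Centers and scales every region column to mean 0, SD 1 (sample SD,
#' n - 1 denominator), the normalization applied before every PCA in the
#' pipeline.
#'
#' @param mat A `regional_matrix` (or plain matrix) with >= 3 rows.
#' @return List with `values` (normalized matrix) and `params` (data frame
#'   of per-region `mean` and `sd`).
#' @export
zscore_regions <- function(mat) {
  x <- unclass(mat)
  if (nrow(x) < 3) stop("need at least 3 subjects to normalize")
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  zero <- colnames(x)[sd == 0]
  if (length(zero))
    stop("zero-variance region(s): ", paste(zero, collapse = ", "))
  z <- sweep(sweep(x, 2, mu), 2, sd, "/")
  list(values = z,
       params = data.frame(region = colnames(x), mean = mu, sd = sd,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Principal component analysis of a normalized regional matrix
#'
#' Computes the top-`K` principal components by singular value
#' decomposition of the column-centered matrix.  Loadings are the
#' unit-norm eigenvectors of the sample covariance; scores are the data
#' projected onto them; `variance_explained[k]` is eigenvalue k over the
#' trace of the covariance.  Signs follow [align_signs()] with the
#' `"mean_positive"`/`"max_abs_positive"` convention unless `align = FALSE`.
#'
#' Degenerate (tied) eigenvalues are returned in the arbitrary but
#' deterministic order produced by LAPACK; ties are broken by input column
#' order.
#'
#' @param normalized Matrix (subjects x regions), typically the `values`
#'   from [zscore_regions()].  Columns are re-centered internally, a no-op
#'   for z-scored input.
#' @param K Number of components, `2 <= K <= min(n - 1, p)` (default 2).
#' @param group_label Optional label stored in the result (placement or
#'   hemisphere tag).
#' @param align Apply the deterministic sign rule (default `TRUE`).
#' @return A `pca_result`: list with `loadings` (regions x K, unit-norm
#'   columns), `scores` (subjects x K), `variance_explained` (K fractions),
#'   `all_variance` (all eigenvalue fractions), `center`, `group_label`,
#'   `sign_rule`.
#' @export
fit_pca <- function(normalized, K = 2, group_label = NA_character_,
                    align = TRUE) {
  x <- unclass(normalized)
  n <- nrow(x); p <- ncol(x)
  if (K < 1 || K > min(n - 1, p))
    stop("K must be between 1 and min(n_subjects - 1, n_regions) = ",
         min(n - 1, p))
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)
  ev <- sv$d^2 / (n - 1)                      # covariance eigenvalues
  total <- sum(ev)
  loadings <- sv$v[, seq_len(K), drop = FALSE]
  scores <- xc %*% loadings
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(K)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(K)))
  res <- structure(list(loadings = loadings, scores = scores,
                        variance_explained = ev[seq_len(K)] / total,
                        all_variance = ev / total,
                        center = ctr,
                        group_label = group_label,
                        sign_rule = "none"),
                   class = "pca_result")
  if (align) res <- align_signs(res) else res
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", ")
  cat(sprintf("PCA [%s]: %d regions, %d subjects, %d components (%s variance)\n",
              x$group_label, nrow(x$loadings), nrow(x$scores),
              ncol(x$loadings), ve))
  invisible(x)
}

#' Elbow (scree) selection of the number of components
#'
#' Returns the position of the maximal second difference of the scree
#' curve (the elbow), floored at 2.  If the curve has no pronounced elbow
#' (maximal second difference below 0.001) the floor value 2 is returned
#' with a warning.  The default pipeline fixes K = 2; this selector is
#' available for checking that choice.
#'
#' @param variance_explained All eigenvalue fractions (length >= 3),
#'   non-increasing.
#' @return Integer >= 2.
#' @export
select_k_scree <- function(variance_explained) {
  f <- as.numeric(variance_explained)
  if (length(f) < 3) stop("need at least 3 variance fractions")
  m <- length(f) - 1
  # second difference at interior positions k = 2 .. m
  k <- 2:m
  d2 <- f[k - 1] - 2 * f[k] + f[k + 1]
  if (max(d2) < 1e-3) {
    warning("no clear elbow in the scree curve; returning the floor K = 2")
    return(2L)
  }
  max(2L, k[which.max(d2)])
}

#' Deterministic sign alignment of principal components
#'
#' Eigenvector sign is arbitrary; this fixes it.  Under `"mean_positive"`
#' PC1 is flipped so its mean loading is positive (the global
#' volume-increase factor then reads as positive everywhere); under
#' `"max_abs_positive"` (applied to PCs >= 2) a component is flipped so
#' its largest-magnitude loading is positive.  Scores flip with their
#' loadings, so the reconstruction `scores %*% t(loadings)` is unchanged.
#' The default applies `mean_positive` to PC1 and `max_abs_positive` to
#' the rest; alignment is idempotent.
#'
#' @param result A `pca_result`.
#' @param rule `"default"`, `"mean_positive"` (all PCs) or
#'   `"max_abs_positive"` (all PCs).
#' @return The sign-aligned `pca_result`.
#' @export
align_signs <- function(result, rule = c("default", "mean_positive",
                                         "max_abs_positive")) {
  rule <- match.arg(rule)
  L <- result$loadings
  for (k in seq_len(ncol(L))) {
    use_mean <- switch(rule,
                       default = k == 1,
                       mean_positive = TRUE,
                       max_abs_positive = FALSE)
    crit <- if (use_mean) mean(L[, k]) else L[which.max(abs(L[, k])), k]
    if (crit < 0) {
      result$loadings[, k] <- -result$loadings[, k]
      result$scores[, k] <- -result$scores[, k]
    }
  }
  result$sign_rule <- rule
  result
}

#' Orient components towards a reference map
#'
#' Flips any component whose loadings correlate negatively with a
#' reference map (scores flip consistently, leaving the reconstruction
#' unchanged).  Similarity statistics use |r| and are unaffected; the
#' orientation only fixes the sign of downstream score coefficients, e.g.
#' so that "higher expression of the reference-like pattern" reads as a
#' positive score.  Purely a sign convention: no reference information
#' enters the decomposition itself.
#'
#' @param result A `pca_result`.
#' @param reference A `reference_map` or numeric vector aligned to the
#'   result's regions.
#' @param components Which components to orient (default: all).
#' @return The re-oriented `pca_result` (`sign_rule` records the step).
#' @export
orient_to_reference <- function(result, reference,
                                components = seq_len(ncol(result$loadings))) {
  ref <- ref_values(reference)
  for (k in components) {
    if (stats::cor(result$loadings[, k], ref) < 0) {
      result$loadings[, k] <- -result$loadings[, k]
      result$scores[, k] <- -result$scores[, k]
    }
  }
  result$sign_rule <- paste0(result$sign_rule, "+reference_oriented")
  result
}

#' Hemisphere-restricted PCA
#'
#' Runs the normalization-then-PCA decomposition on the 42 regions of one
#' hemisphere only and compares the result against a whole-brain fit
#' restricted to the same regions: for each component the Pearson
#' correlation between the hemisphere loadings and the whole-brain
#' loadings on those regions (sign-free, reported as signed r with the
#' orientation that maximizes |r| noted by its sign).
#'
#' @param mat A `regional_matrix` over the full atlas (raw, not z-scored).
#' @param atlas A `region_atlas`.
#' @param side `"left"` or `"right"`.
#' @param K Components (default 2).
#' @param whole_brain Optional whole-brain `pca_result` on the same
#'   matrix; if supplied, a `comparison` table of per-component loading
#'   correlations is attached.
#' @param group_label Label for the result.
#' @return A `pca_result` over 42 regions, with a `comparison` data frame
#'   (`component`, `r_loading`) when `whole_brain` is given.
#' @export
hemisphere_pca <- function(mat, atlas, side, K = 2, whole_brain = NULL,
                           group_label = paste0("hemi_", side)) {
  sub_atlas <- hemisphere_subset(atlas, side)
  x <- unclass(mat)[, sub_atlas$name, drop = FALSE]
  z <- zscore_regions(x)
  res <- fit_pca(z$values, K = K, group_label = group_label)
  if (!is.null(whole_brain)) {
    wb <- whole_brain$loadings[sub_atlas$name, , drop = FALSE]
    kk <- min(K, ncol(wb))
    r <- vapply(seq_len(kk), function(k)
      stats::cor(res$loadings[, k], wb[, k]), numeric(1))
    res$comparison <- data.frame(component = paste0("PC", seq_len(kk)),
                                 r_loading = r, stringsAsFactors = FALSE)
  }
  res
}

#' Placement-stratified PCA of a regional matrix
#'
#' Fits one normalization-then-PCA decomposition per electrode-placement
#' group (never pooling placements, to avoid capturing placement-specific
#' differences as components).
#'
#' @param mat A `regional_matrix` aligned to `cohort`.
#' @param cohort An `ect_cohort`.
#' @param K Components per group.
#' @return Named list of `pca_result`, one per placement present.
#' @export
pca_by_placement <- function(mat, cohort, K = 2) {
  stopifnot(identical(rownames(mat), cohort$subject_id))
  groups <- intersect(c("RUL", "BT", "MIX"), unique(cohort$placement))
  out <- lapply(groups, function(g) {
    idx <- cohort$placement == g
    z <- zscore_regions(unclass(mat)[idx, , drop = FALSE])
    fit_pca(z$values, K = K,
            group_label = paste0(g, "_", rm_measure(mat)))
  })
  stats::setNames(out, groups)
}
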