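# Spatial similarity of PC loadings to a reference network map, with
# permutation inference.  Parametric correlation p-values are not valid
# for spatially structured maps, so significance comes from a null built
# by reshuffling baseline scans across subjects within placement group.

ref_values <- function(reference) {
  if (inherits(reference, "reference_map")) reference$values
  else as.numeric(reference)
}

#' Pearson spatial correlation between a loading vector and a reference map
#'
#' @param loadings_pc Numeric vector of per-region loadings.
#' @param reference A `reference_map` or numeric vector, aligned in region
#'   order.
#' @return The Pearson correlation across regions.
#' @export
spatial_r <- function(loadings_pc, reference) {
  y <- ref_values(reference)
  x <- as.numeric(loadings_pc)
  if (length(x) != length(y)) stop("loadings and reference are not aligned")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: spatial correlation undefined")
  stats::cor(x, y)
}

#' Permutation null for loading-reference similarity by baseline reshuffling
#'
#' Chance-level volume-change patterns are generated by reassigning
#' baseline scans across subjects within each placement group:
#' permutation pi gives `dVol*[i, r] = (V2[i, r] - V1[pi(i), r]) /
#' V1[pi(i), r] * 100`.  Each permuted change matrix is re-normalized and
#' re-decomposed by a K-component PCA exactly as the observed data, and
#' the null statistic `max_k |r(loading_k, reference)|` is recorded
#' (component-agnostic and conservative; per-component nulls are kept
#' too).  The p-value uses the add-one rule
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`, so its minimum is
#' `1/(n_perm + 1)` and it is invariant to loading sign.
#'
#' @param v1,v2 Baseline and follow-up volume `regional_matrix` objects
#'   (positive, aligned).
#' @param reference A `reference_map` or aligned numeric vector.
#' @param group_labels Placement label per subject; permutation and PCA
#'   are stratified by it.  Groups need >= 3 subjects.
#' @param K Components per PCA (default 2).
#' @param n_perm Number of permutations (>= 99 for inference; the
#'   identity-only check uses 1).
#' @param seed Integer seed.
#' @param force_identity If `TRUE`, every "permutation" is the identity
#'   (diagnostic: null statistic then equals the observed one).
#' @return A `similarity_result`: per group, observed `r_obs` per
#'   component, per-component permutation p-values, the max-statistic
#'   p-value `p_perm`, a `null_summary` (mean, SD, 95th/99th percentiles
#'   of the null max |r|), and the per-permutation loadings (used by
#'   [head_to_head()]).
#' @export
baseline_shuffle_null <- function(v1, v2, reference, group_labels,
                                  K = 2, n_perm = 199, seed = 1,
                                  force_identity = FALSE) {
  stopifnot(identical(dim(v1), dim(v2)),
            identical(rownames(v1), rownames(v2)))
  if (any(v1 <= 0) || any(v2 <= 0)) stop("volumes must be positive")
  ref <- ref_values(reference)
  groups <- unique(group_labels)
  small <- groups[table(factor(group_labels, groups)) < 3]
  if (length(small))
    stop("placement group(s) with < 3 subjects: ",
         paste(small, collapse = ", "))

  fit_group <- function(m1, m2, perm) {
    dv <- 100 * (m2 - m1[perm, , drop = FALSE]) / m1[perm, , drop = FALSE]
    z <- zscore_regions(dv)
    fit_pca(z$values, K = K, align = FALSE)
  }

  with_seed(seed, {
    out <- lapply(groups, function(g) {
      idx <- which(group_labels == g)
      m1 <- unclass(v1)[idx, , drop = FALSE]
      m2 <- unclass(v2)[idx, , drop = FALSE]
      obs <- fit_group(m1, m2, seq_along(idx))
      r_obs <- vapply(seq_len(K), function(k)
        spatial_r(obs$loadings[, k], ref), numeric(1))
      stat_obs <- max(abs(r_obs))

      null_abs <- matrix(NA_real_, n_perm, K)
      null_loadings <- vector("list", n_perm)
      for (p in seq_len(n_perm)) {
        perm <- if (force_identity) seq_along(idx) else sample(length(idx))
        fit <- fit_group(m1, m2, perm)
        null_loadings[[p]] <- fit$loadings
        null_abs[p, ] <- vapply(seq_len(K), function(k)
          abs(spatial_r(fit$loadings[, k], ref)), numeric(1))
      }
      null_stat <- apply(null_abs, 1, max)
      list(group = g,
           n_subjects = length(idx),
           n_regions = length(ref),
           r_obs = stats::setNames(r_obs, paste0("PC", seq_len(K))),
           p_per_component = stats::setNames(
             (1 + colSums(null_abs >= rep(abs(r_obs), each = n_perm))) /
               (1 + n_perm), paste0("PC", seq_len(K))),
           p_perm = (1 + sum(null_stat >= stat_obs)) / (1 + n_perm),
           stat_obs = stat_obs,
           null_summary = c(mean = mean(null_stat), sd = stats::sd(null_stat),
                            q95 = unname(stats::quantile(null_stat, 0.95)),
                            q99 = unname(stats::quantile(null_stat, 0.99))),
           n_perm = n_perm,
           statistic_def = "max over components 1..K of |Pearson r(loading, reference)|",
           observed_loadings = obs$loadings,
           null_loadings = null_loadings)
    })
    structure(stats::setNames(out, groups), class = "similarity_result")
  })
}

#' @export
print.similarity_result <- function(x, ...) {
  for (g in names(x)) {
    e <- x[[g]]
    cat(sprintf("[%s] n=%d, r_obs: %s; p_perm(max|r|)=%.4g (%d perms)\n",
                g, e$n_subjects,
                paste(sprintf("%s=%.3f", names(e$r_obs), e$r_obs),
                      collapse = ", "),
                e$p_perm, e$n_perm))
  }
  invisible(x)
}

#' Head-to-head regression of the reference map on PC1 and PC2 loadings
#'
#' Fits `reference ~ PC1 + PC2` across regions by ordinary least squares
#' and quantifies each component's distinct contribution: partial
#' t-statistics and the nested-model R-squared gains (of adding PC1 to a
#' PC2-only model and vice versa).  If per-permutation loadings from
#' [baseline_shuffle_null()] are supplied, the observed PC2-over-PC1
#' advantage `|t_PC2| - |t_PC1|` is compared against the same quantity
#' recomputed on every permutation's loadings;
#' `pc2_dominance_fraction` is the fraction of permutations in which the
#' observed advantage exceeds the permuted one.
#'
#' @param loadings_pc1,loadings_pc2 Aligned per-region loading vectors.
#' @param reference A `reference_map` or aligned numeric vector.
#' @param null_loadings Optional list of regions-x-K loading matrices
#'   (one per permutation), as stored in a `similarity_result` entry.
#' @return A `head_to_head_result`: `coefficients` (term, beta, se, t, p),
#'   `r2_full`, `dr2_add_pc1`, `dr2_add_pc2`, and
#'   `pc2_dominance_fraction` (NA without permutations).
#' @export
head_to_head <- function(loadings_pc1, loadings_pc2, reference,
                         null_loadings = NULL) {
  y <- ref_values(reference)
  x1 <- as.numeric(loadings_pc1); x2 <- as.numeric(loadings_pc2)
  if (length(x1) != length(y) || length(x2) != length(y))
    stop("loadings and reference are not aligned")
  if (abs(stats::cor(x1, x2)) > 0.999)
    stop("PC1 and PC2 loadings are collinear (|r| > 0.999)")

  r2_single <- function(x) {
    res <- stats::lm.fit(cbind(1, x), y)$residuals
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  fit_terms <- function(a, b) {
    f <- ols_fit(y, data.frame(PC1 = a, PC2 = b))
    r2_1 <- r2_single(a)
    r2_2 <- r2_single(b)
    list(tab = f, r2_full = f$r_squared,
         dr2_add_pc1 = f$r_squared - r2_2,
         dr2_add_pc2 = f$r_squared - r2_1)
  }
  obs <- fit_terms(x1, x2)
  tt <- obs$tab$coefficients
  adv_obs <- abs(tt$t[tt$term == "PC2"]) - abs(tt$t[tt$term == "PC1"])

  frac <- NA_real_
  if (!is.null(null_loadings) && length(null_loadings)) {
    adv_null <- vapply(null_loadings, function(L) {
      f <- fit_terms(L[, 1], L[, 2])
      ct <- f$tab$coefficients
      abs(ct$t[ct$term == "PC2"]) - abs(ct$t[ct$term == "PC1"])
    }, numeric(1))
    frac <- mean(adv_obs > adv_null)
  }
  structure(list(coefficients = obs$tab$coefficients,
                 r2_full = obs$r2_full,
                 dr2_add_pc1 = max(obs$dr2_add_pc1, 0),
                 dr2_add_pc2 = max(obs$dr2_add_pc2, 0),
                 pc2_advantage = adv_obs,
                 pc2_dominance_fraction = frac),
            class = "head_to_head_result")
}

#' @export
print.head_to_head_result <- function(x, ...) {
  cat("Head-to-head: reference ~ PC1 + PC2 across regions\n")
  print(x$coefficients, digits = 3)
  cat(sprintf("R2 full = %.3f; dR2(add PC1|PC2) = %.3f; dR2(add PC2|PC1) = %.3f\n",
              x$r2_full, x$dr2_add_pc1, x$dr2_add_pc2))
  if (!is.na(x$pc2_dominance_fraction))
    cat(sprintf("PC2 dominance fraction across permutations: %.3f\n",
                x$pc2_dominance_fraction))
  invisible(x)
}
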