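# subjects x regions container with a declared measure; all regional data
# (volume change %, EF V/m, raw volumes mm^3) flow through this class.

.valid_measures <- c("dvol_percent", "ef_vpm", "volume_mm3")

#' Construct a regional data matrix
#'
#' A `regional_matrix` is a numeric subjects-by-regions matrix with subject
#' ids as row names, region names (in atlas order) as column names, and a
#' declared measure: `"dvol_percent"` (longitudinal volume change, %),
#' `"ef_vpm"` (electric-field amplitude, V/m) or `"volume_mm3"`.
#'
#' @param values Numeric matrix, subjects x regions; no missing values.
#' @param subject_ids Character vector of unique subject ids (defaults to
#'   the row names of `values`).
#' @param region_names Character vector of region names (defaults to the
#'   column names of `values`).
#' @param measure One of `r paste0('"', .valid_measures, '"', collapse = ", ")`.
#' @return A `regional_matrix` object.
#' @export
regional_matrix <- function(values, subject_ids = rownames(values),
                            region_names = colnames(values),
                            measure = c("dvol_percent", "ef_vpm", "volume_mm3")) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  if (is.null(subject_ids) || is.null(region_names))
    stop("subject_ids and region_names are required")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (length(subject_ids) != nrow(values) ||
      length(region_names) != ncol(values))
    stop("dimension mismatch between values and id/name vectors")
  if (anyNA(values) || !all(is.finite(values)))
    stop("regional matrix contains missing or non-finite values")
  dimnames(values) <- list(as.character(subject_ids),
                           as.character(region_names))
  structure(values, measure = measure,
            class = c("regional_matrix", "matrix", "array"))
}

#' @export
print.regional_matrix <- function(x, ...) {
  cat(sprintf("Regional matrix [%s]: %d subjects x %d regions\n",
              attr(x, "measure"), nrow(x), ncol(x)))
  invisible(x)
}

rm_measure <- function(x) attr(x, "measure")

# check that a matrix is aligned to an atlas (same region names, same order)
check_atlas_alignment <- function(mat, atlas) {
  if (!identical(colnames(mat), atlas$name))
    stop("region columns do not match the atlas order")
  invisible(TRUE)
}

#' Write a regional matrix to CSV
#'
#' One row per subject; first column `subject_id`, then one column per
#' region in atlas order.  Numbers carry 10 significant digits.
#'
#' @param mat A `regional_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regional_csv <- function(mat, path) {
  stopifnot(inherits(mat, "regional_matrix"))
  df <- data.frame(subject_id = rownames(mat),
                   signif(unclass(mat), 10),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a regional matrix from CSV
#'
#' The file must have a `subject_id` column and one numeric column per
#' atlas region (any column order; columns are reordered to atlas order).
#' Unknown or missing region columns, duplicate subject ids and
#' non-numeric cells are errors naming the offenders.
#'
#' @param path CSV file path.
#' @param atlas A `region_atlas` defining the expected regions.
#' @param measure The measure declared for the returned matrix.
#' @return A `regional_matrix` in atlas region order.
#' @export
load_regional_csv <- function(path, atlas,
                              measure = c("dvol_percent", "ef_vpm", "volume_mm3")) {
  measure <- match.arg(measure)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("CSV has no subject_id column: ", path)
  regions <- setdiff(names(df), "subject_id")
  missing <- setdiff(atlas$name, regions)
  if (length(missing))
    stop("CSV missing region columns: ", paste(missing, collapse = ", "))
  unknown <- setdiff(regions, atlas$name)
  if (length(unknown))
    stop("CSV has unknown region columns: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject ids: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  vals <- df[, atlas$name, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric region columns: ", paste(bad, collapse = ", "))
  regional_matrix(as.matrix(vals), subject_ids = df$subject_id,
                  region_names = atlas$name, measure = measure)
}
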