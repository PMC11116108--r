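# 85-region parcellation: 33 cortical + 8 subcortical + cerebellum per
# hemisphere, plus brainstem.  Region order is left cortical, left
# subcortical, left cerebellum, the right hemisphere mirrored, brainstem last.

# Desikan-Killiany cortical labels (34-label scheme minus frontalpole,
# giving the 33 used throughout).  Coordinates are approximate MNI-like
# centroids (mm) for the LEFT hemisphere; right homologs mirror in x.
.cortical_regions <- function() {
  tab <- matrix(c(
    "bankssts",                 -54, -45,   8,
    "caudalanteriorcingulate",   -5,  18,  30,
    "caudalmiddlefrontal",      -36,  12,  48,
    "cuneus",                    -7, -80,  27,
    "entorhinal",               -24, -10, -30,
    "fusiform",                 -36, -44, -19,
    "inferiorparietal",         -42, -62,  36,
    "inferiortemporal",         -50, -32, -23,
    "isthmuscingulate",          -8, -45,  24,
    "lateraloccipital",         -31, -86,   4,
    "lateralorbitofrontal",     -25,  30, -16,
    "lingual",                  -15, -67,  -5,
    "medialorbitofrontal",       -7,  36, -16,
    "middletemporal",           -57, -27, -12,
    "parahippocampal",          -25, -32, -18,
    "paracentral",               -9, -25,  58,
    "parsopercularis",          -48,  14,  14,
    "parsorbitalis",            -44,  32,  -9,
    "parstriangularis",         -46,  30,   6,
    "pericalcarine",            -11, -79,   7,
    "postcentral",              -42, -25,  48,
    "posteriorcingulate",        -6, -26,  38,
    "precentral",               -39,  -8,  48,
    "precuneus",                 -9, -59,  41,
    "rostralanteriorcingulate",  -6,  36,   8,
    "rostralmiddlefrontal",     -33,  43,  20,
    "superiorfrontal",          -12,  30,  48,
    "superiorparietal",         -25, -60,  54,
    "superiortemporal",         -55, -16,   0,
    "supramarginal",            -54, -40,  30,
    "temporalpole",             -32,  12, -34,
    "transversetemporal",       -45, -24,  10,
    "insula",                   -36,   1,   4
  ), ncol = 4, byrow = TRUE)
  data.frame(name = tab[, 1],
             x = as.numeric(tab[, 2]),
             y = as.numeric(tab[, 3]),
             z = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
}

# aseg subcortical structures
.subcortical_regions <- function() {
  tab <- matrix(c(
    "thalamus",     -11, -20,   9,
    "caudate",      -13,  11,  10,
    "putamen",      -25,   2,   1,
    "pallidum",     -19,  -4,  -1,
    "hippocampus",  -26, -22, -14,
    "amygdala",     -23,  -4, -19,
    "accumbens",     -9,  11,  -7,
    "ventraldc",    -10, -13,  -8
  ), ncol = 4, byrow = TRUE)
  data.frame(name = tab[, 1],
             x = as.numeric(tab[, 2]),
             y = as.numeric(tab[, 3]),
             z = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
}

#' Build the canonical 85-region atlas
#'
#' Constructs the fixed parcellation used by every other function in the
#' package: 33 Desikan-Killiany cortical regions and 8 subcortical
#' structures per hemisphere, plus left and right cerebellum and the
#' brainstem (85 regions in total).  Region order is deterministic:
#' left cortical, left subcortical, left cerebellum, then the right
#' hemisphere in the same order, then brainstem.
#'
#' Centroid coordinates are fixed synthetic MNI-like positions (mm); they
#' exist only to drive the electric-field surrogate and are not measured
#' values.  Left/right homologs mirror in the x coordinate.
#'
#' @return A `region_atlas` object: a data frame with columns `name`
#'   (e.g. `"hippocampus_lh"`), `hemisphere` (`left`/`right`/`midline`),
#'   `tissue_class` (`cortical`/`subcortical`/`cerebellum`/`brainstem`),
#'   and centroid coordinates `x`, `y`, `z`.
#' @examples
#' atlas <- build_atlas()
#' nrow(atlas)              # 85
#' table(atlas$hemisphere)  # 42 left, 42 right, 1 midline
#' @export
build_atlas <- function() {
  ctx <- .cortical_regions()
  sub <- .subcortical_regions()
  one_side <- function(side) {
    sgn <- if (side == "left") 1 else -1
    suf <- if (side == "left") "_lh" else "_rh"
    rbind(
      data.frame(name = paste0(ctx$name, suf), hemisphere = side,
                 tissue_class = "cortical",
                 x = sgn * ctx$x, y = ctx$y, z = ctx$z,
                 stringsAsFactors = FALSE),
      data.frame(name = paste0(sub$name, suf), hemisphere = side,
                 tissue_class = "subcortical",
                 x = sgn * sub$x, y = sub$y, z = sub$z,
                 stringsAsFactors = FALSE),
      data.frame(name = paste0("cerebellum", suf), hemisphere = side,
                 tissue_class = "cerebellum",
                 x = sgn * -25, y = -60, z = -35,
                 stringsAsFactors = FALSE)
    )
  }
  atlas <- rbind(
    one_side("left"),
    one_side("right"),
    data.frame(name = "brainstem", hemisphere = "midline",
               tissue_class = "brainstem",
               x = 0, y = -30, z = -30, stringsAsFactors = FALSE)
  )
  rownames(atlas) <- NULL
  stopifnot(nrow(atlas) == 85L, !anyDuplicated(atlas$name))
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}

#' Extract one hemisphere of an atlas
#'
#' Returns the 42-region subset for the requested side, preserving the
#' atlas order.  The homolog pairing (left name, right name) needed for
#' cross-hemisphere loading comparisons is available via
#' [homolog_pairs()].
#'
#' @param atlas A `region_atlas` from [build_atlas()].
#' @param side `"left"` or `"right"`.
#' @return A `region_atlas` with 42 rows.
#' @export
hemisphere_subset <- function(atlas, side) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (!side %in% c("left", "right"))
    stop("unknown side: ", side, " (expected 'left' or 'right')")
  out <- atlas[atlas$hemisphere == side, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_atlas", "data.frame")
  out
}

#' Homolog pairing table
#'
#' @param atlas A `region_atlas`.
#' @return A data frame with columns `left` and `right`, one row per
#'   homologous region pair (42 rows for the full atlas).
#' @export
homolog_pairs <- function(atlas) {
  lh <- hemisphere_subset(atlas, "left")
  rh <- hemisphere_subset(atlas, "right")
  stem_l <- sub("_lh$", "", lh$name)
  stem_r <- sub("_rh$", "", rh$name)
  stopifnot(identical(stem_l, stem_r))
  data.frame(left = lh$name, right = rh$name, stringsAsFactors = FALSE)
}

#' Write / read an atlas as CSV
#'
#' Columns: name, hemisphere, tissue_class, x, y, z.
#'
#' @param atlas A `region_atlas`.
#' @param path File path.
#' @return `read_atlas_csv` returns a `region_atlas`; `write_atlas_csv`
#'   returns `path` invisibly.
#' @export
write_atlas_csv <- function(atlas, path) {
  stopifnot(inherits(atlas, "region_atlas"))
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_csv
#' @export
read_atlas_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "hemisphere", "tissue_class", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("atlas CSV missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  class(df) <- c("region_atlas", "data.frame")
  df
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("Region atlas: %d regions (%d left, %d right, %d midline)\n",
              nrow(x), sum(x$hemisphere == "left"),
              sum(x$hemisphere == "right"), sum(x$hemisphere == "midline")))
  invisible(x)
}
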