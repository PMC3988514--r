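# Disease-VOI diagnosis-support indices from a Z-score map.
#
# Given a Z map (positive = hypoperfusion) and a disease-specific VOI mask,
# three indices summarize the deficit: Severity (mean suprathreshold Z in
# the VOI), Extent (% of VOI voxels at or above threshold) and Ratio (the
# VOI's suprathreshold fraction over the whole brain's). The voxel
# threshold defaults to Z >= 2.

#' Severity / Extent / Ratio indices over a disease VOI
#'
#' @param zmap A [zscore_map] using the positive-=-decrease convention.
#' @param voi_mask 3-D logical array, a subset of the Z map's brain mask.
#' @param z_threshold Voxel threshold defining the deficit (default 2).
#' @param ratio_as_percent If `TRUE` report Ratio as a percentage instead of
#'   a dimensionless quotient of the two extent fractions.
#' @return An object of class `sva_result` with fields `severity` (unitless
#'   Z; 0 when no VOI voxel is suprathreshold), `extent` (% of VOI voxels),
#'   `ratio`, `z_threshold`, `voi_voxels`, `brain_extent_percent`.
#' @export
sva_indices <- function(zmap, voi_mask, z_threshold = 2,
                        ratio_as_percent = FALSE) {
  stopifnot(inherits(zmap, "zscore_map"))
  if (!identical(dim(zmap$z), dim(voi_mask))) stop("grid mismatch")
  voi <- voi_mask > 0
  if (!any(voi)) stop("the VOI mask is empty")
  if (any(voi & !zmap$brain_mask))
    stop("the VOI mask must lie inside the brain mask")
  zv <- zmap$z[voi]
  hit <- zv >= z_threshold
  severity <- if (any(hit)) mean(zv[hit]) else 0
  extent_frac <- mean(hit)
  brain_frac <- mean(zmap$z[zmap$brain_mask] >= z_threshold)
  ratio <- if (brain_frac > 0) extent_frac / brain_frac else 0
  structure(
    list(severity = severity, extent = 100 * extent_frac,
         ratio = if (ratio_as_percent) 100 * ratio else ratio,
         ratio_as_percent = ratio_as_percent,
         z_threshold = z_threshold, voi_voxels = sum(voi),
         brain_extent_percent = 100 * brain_frac,
         voi_id = attr(voi_mask, "voi_id") %||% "voi",
         definition = paste(
           "severity = mean suprathreshold Z in VOI;",
           "extent = % suprathreshold VOI voxels;",
           "ratio = VOI extent fraction / whole-brain extent fraction")),
    class = "sva_result")
}

#' @export
print.sva_result <- function(x, ...) {
  cat(sprintf(
    "<sva_result '%s'> Severity %.3f  Extent %.2f%%  Ratio %.3f%s (Z >= %.3g)\n",
    x$voi_id, x$severity, x$extent, x$ratio,
    if (x$ratio_as_percent) "%" else "", x$z_threshold))
  invisible(x)
}

#' Build a VOI mask from an atlas
#'
#' Union of the listed atlas regions as a binary mask.
#'
#' @param atlas A `region_atlas` (see [make_region_atlas()]) or a bare
#'   integer label array.
#' @param region_ids Integer label values or, for a `region_atlas`, region
#'   names. Repeated ids are allowed (idempotent union).
#' @return 3-D logical array with the union of the regions.
#' @export
make_sva_mask <- function(atlas, region_ids) {
  if (inherits(atlas, "region_atlas")) {
    labels <- atlas$labels
    if (is.character(region_ids)) {
      unknown <- setdiff(region_ids, names(atlas$regions))
      if (length(unknown))
        stop("unknown region(s): ", paste(unknown, collapse = ", "))
      region_ids <- atlas$regions[region_ids]
    }
  } else labels <- atlas
  region_ids <- unique(as.integer(region_ids))
  present <- unique(as.integer(labels))
  if (!all(region_ids %in% present))
    stop("unknown region id(s): ",
         paste(setdiff(region_ids, present), collapse = ", "))
  array(labels %in% region_ids, dim(labels))
}

#' Synthetic posterior disease VOI
#'
#' A posterior medial wedge of the brain mask, a synthetic stand-in for the
#' disease-specific (posterior cingulate / precuneus) VOI used by the
#' clinical index software, whose atlas is proprietary.
#'
#' @param brain_mask 3-D logical array.
#' @param voxel_size_mm Voxel size, mm.
#' @return 3-D logical array (subset of `brain_mask`).
#' @export
default_sva_voi <- function(brain_mask, voxel_size_mm) {
  co <- coord_arrays(dim(brain_mask), voxel_size_mm)
  half <- dim(brain_mask) * check_voxel(voxel_size_mm) / 2
  yn <- co$y / half[2]; xn <- co$x / half[1]; zn <- co$z / half[3]
  voi <- brain_mask & yn <= -0.25 & abs(xn) <= 0.35 & zn >= -0.15 & zn <= 0.45
  attr(voi, "voi_id") <- "posterior_medial_synthetic"
  voi
}
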