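# Voxel-wise count-ratio compensation between two cameras.
#
# The compensation ("count ratio") image is the voxel-wise ratio of a common
# object imaged on the reference camera (the one that built the normal
# database) and on the target camera (the clinical one). Multiplying a
# target-camera subject scan by the ratio harmonizes it to the reference
# camera. Ratios are only formed where both mean images carry appreciable
# counts; elsewhere the map is the neutral element 1.

#' Build a compensation map from paired acquisitions
#'
#' Averages each camera's acquisitions of the common object (the physical
#' protocol uses three per camera), optionally Gaussian-smooths both means,
#' and forms the voxel-wise ratio reference/target wherever both means reach
#' `count_floor` times their own whole-support mean. Outside that validity
#' mask the ratio is 1.
#'
#' @param reference_imgs A [subject_volume] or list of them from the
#'   reference camera.
#' @param target_imgs Same, from the target camera; lists may have unequal
#'   lengths.
#' @param count_floor Fraction of the whole-support mean below which a voxel
#'   is excluded from the ratio (guards near-zero denominators).
#' @param smoothing_fwhm_mm Gaussian FWHM applied to both mean images before
#'   the ratio; 0 (default) keeps the operation a literal per-voxel ratio.
#' @param source Provenance label (`"hoffman"`, `"brain3d"`, `"pool"`,
#'   `"normal_spect"`, ...).
#' @return An object of class `compensation_map` with fields `ratio`,
#'   `valid_mask`, `source`, `n_reference`, `n_target`,
#'   `smoothing_fwhm_mm`.
#' @export
build_compensation_map <- function(reference_imgs, target_imgs,
                                   count_floor = 0.05,
                                   smoothing_fwhm_mm = 0,
                                   source = "unknown") {
  as_list <- function(x) if (inherits(x, "subject_volume")) list(x) else x
  refs <- as_list(reference_imgs)
  tgts <- as_list(target_imgs)
  if (length(refs) < 1 || length(tgts) < 1)
    stop("need at least one acquisition per camera")
  if (count_floor < 0 || count_floor >= 1)
    stop("`count_floor` must lie in [0, 1)")
  voxel <- refs[[1]]$voxel_size_mm
  mean_of <- function(lst) {
    acc <- array(0, dim(lst[[1]]$counts))
    for (s in lst) {
      if (!identical(dim(s$counts), dim(acc)))
        stop("all images must share the common grid")
      acc <- acc + s$counts
    }
    acc / length(lst)
  }
  ref_mean <- mean_of(refs)
  tgt_mean <- mean_of(tgts)
  if (!identical(dim(ref_mean), dim(tgt_mean)))
    stop("reference and target images must share the common grid")
  if (smoothing_fwhm_mm > 0) {
    ref_mean <- gaussian_smooth(ref_mean, smoothing_fwhm_mm, voxel)
    tgt_mean <- gaussian_smooth(tgt_mean, smoothing_fwhm_mm, voxel)
  }
  floor_of <- function(m) {
    pos <- m > 0
    if (!any(pos)) return(Inf)
    count_floor * mean(m[pos])
  }
  valid <- ref_mean >= floor_of(ref_mean) & tgt_mean >= floor_of(tgt_mean)
  if (!any(valid))
    stop("reference and target supports do not overlap")
  ratio <- array(1, dim(ref_mean))
  ratio[valid] <- ref_mean[valid] / tgt_mean[valid]
  structure(
    list(ratio = ratio, valid_mask = valid, source = source,
         n_reference = length(refs), n_target = length(tgts),
         smoothing_fwhm_mm = smoothing_fwhm_mm, voxel_size_mm = voxel,
         reference_camera = refs[[1]]$camera_id,
         target_camera = tgts[[1]]$camera_id),
    class = "compensation_map")
}

#' @export
print.compensation_map <- function(x, ...) {
  r <- x$ratio[x$valid_mask]
  cat(sprintf(
    "<compensation_map '%s'> %s/%s, %d/%d acquisitions averaged\n",
    x$source, x$reference_camera, x$target_camera,
    x$n_reference, x$n_target))
  cat(sprintf("  valid voxels: %d; ratio range %.3f..%.3f (median %.3f)\n",
              sum(x$valid_mask), min(r), max(r), stats::median(r)))
  invisible(x)
}

#' Apply a compensation map to a subject volume
#'
#' Multiplies every voxel of the subject's counts by the map's ratio (the
#' neutral value 1 outside the validity mask leaves those voxels untouched).
#'
#' @param subject A [subject_volume] from the map's target camera.
#' @param comp A [compensation_map].
#' @return A new [subject_volume]; the input is not modified.
#' @export
apply_compensation <- function(subject, comp) {
  stopifnot(inherits(subject, "subject_volume"),
            inherits(comp, "compensation_map"))
  if (!identical(dim(subject$counts), dim(comp$ratio)))
    stop("subject and compensation map are on different grids")
  out <- subject
  out$counts <- subject$counts * comp$ratio
  out$meta$compensated_by <- comp$source
  out
}

#' Inverse of a compensation map
#'
#' The derived map with ratio `1/ratio` on the validity mask (and 1
#' elsewhere), mapping reference-camera images onto the target camera.
#'
#' @param comp A [compensation_map].
#' @return A [compensation_map] in the opposite direction.
#' @export
invert_compensation <- function(comp) {
  stopifnot(inherits(comp, "compensation_map"))
  out <- comp
  out$ratio[comp$valid_mask] <- 1 / comp$ratio[comp$valid_mask]
  out$source <- paste0(comp$source, "_inverse")
  out$reference_camera <- comp$target_camera
  out$target_camera <- comp$reference_camera
  n <- out$n_reference; out$n_reference <- out$n_target; out$n_target <- n
  out
}
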