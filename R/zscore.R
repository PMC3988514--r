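# Global count normalization, normal-database construction and voxel-wise
# Z-score mapping.
#
# Conventions follow the standard Z-score imaging workflow: each volume is
# smoothed and proportionally scaled so its brain-mask mean equals a fixed
# target (50 by convention), the normal database (NDB) stores the voxel-wise
# mean and sample SD of a normalized cohort, and the Z map is
# (NDB mean - subject)/(NDB SD) with POSITIVE values flagging count decrease
# (hypoperfusion), matching the clinical display convention.

#' Proportional global count normalization
#'
#' Scales a subject volume so that its mean over the brain mask equals
#' `target` exactly. Idempotent.
#'
#' @param subject A [subject_volume] (or bare 3-D array).
#' @param brain_mask 3-D logical array.
#' @param target Target brain-mask mean (50 by the usual convention).
#' @return Same type as `subject`.
#' @export
global_normalize <- function(subject, brain_mask, target = 50) {
  arr <- if (inherits(subject, "subject_volume")) subject$counts else subject
  if (!identical(dim(arr), dim(brain_mask))) stop("grid mismatch")
  if (!any(brain_mask)) stop("brain mask is empty")
  m <- mean(arr[brain_mask])
  if (m <= 0) stop("mean counts over the brain mask are not positive")
  arr <- arr * (target / m)
  if (inherits(subject, "subject_volume")) {
    subject$counts <- arr
    subject$meta$normalization_target <- target
    subject
  } else arr
}

#' Smooth and normalize a subject for Z-scoring
#'
#' The preprocessing every volume receives before entering (or being scored
#' against) a normal database: Gaussian smoothing followed by
#' [global_normalize()]. Subjects scored against an NDB must be preprocessed
#' with the NDB's own parameters.
#'
#' @param subject A [subject_volume].
#' @param brain_mask 3-D logical array.
#' @param smoothing_fwhm_mm Gaussian FWHM, mm.
#' @param target Normalization target.
#' @return A preprocessed [subject_volume].
#' @export
preprocess_subject <- function(subject, brain_mask, smoothing_fwhm_mm = 12,
                               target = 50) {
  stopifnot(inherits(subject, "subject_volume"))
  subject$counts <- gaussian_smooth(subject$counts, smoothing_fwhm_mm,
                                    subject$voxel_size_mm)
  subject$counts[subject$counts < 0] <- 0
  global_normalize(subject, brain_mask, target)
}

#' Build a normal database
#'
#' Each subject is smoothed (Gaussian, `smoothing_fwhm_mm`) and globally
#' normalized, then the voxel-wise mean and sample SD (n-1 denominator) are
#' taken. The SD is floored at `sd_floor_fraction` times the mean SD over
#' the brain mask (falling back to the same fraction of the normalization
#' target for a degenerate zero-variance cohort), which keeps Z-scores
#' finite everywhere.
#'
#' @param subjects List of [subject_volume]s on the common grid (n >= 2).
#' @param brain_mask 3-D logical array.
#' @param smoothing_fwhm_mm Gaussian FWHM applied to each subject, mm.
#' @param sd_floor_fraction SD floor as a fraction of the mean masked SD.
#' @param normalization_target Brain-mask mean after normalization.
#' @return An object of class `ndb` with fields `mean`, `sd`, `n`,
#'   `brain_mask`, `normalization_target`, `smoothing_fwhm_mm`, `camera_id`.
#' @export
build_ndb <- function(subjects, brain_mask, smoothing_fwhm_mm = 12,
                      sd_floor_fraction = 0.1, normalization_target = 50) {
  if (length(subjects) < 2) stop("an NDB needs at least 2 subjects")
  n <- length(subjects)
  prepped <- lapply(subjects, preprocess_subject, brain_mask = brain_mask,
                    smoothing_fwhm_mm = smoothing_fwhm_mm,
                    target = normalization_target)
  X <- vapply(prepped, function(s) as.vector(s$counts),
              numeric(length(brain_mask)))
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  mean_sd <- mean(sdv[as.vector(brain_mask)])
  floor_val <- sd_floor_fraction *
    (if (mean_sd > 0) mean_sd else normalization_target)
  sdv <- pmax(sdv, floor_val)
  structure(
    list(mean = array(mu, dim(brain_mask)),
         sd = array(sdv, dim(brain_mask)),
         n = n, brain_mask = brain_mask,
         normalization_target = normalization_target,
         smoothing_fwhm_mm = smoothing_fwhm_mm,
         sd_floor = floor_val,
         camera_id = subjects[[1]]$camera_id,
         voxel_size_mm = subjects[[1]]$voxel_size_mm),
    class = "ndb")
}

#' @export
print.ndb <- function(x, ...) {
  cat(sprintf(
    "<ndb> n = %d (camera %s), target %.4g, smoothing %.4g mm FWHM\n",
    x$n, x$camera_id, x$normalization_target, x$smoothing_fwhm_mm))
  m <- x$brain_mask
  cat(sprintf("  brain mask: %d voxels; voxel CV (sd/mean) median %.3f\n",
              sum(m), stats::median(x$sd[m] / pmax(x$mean[m], 1e-12))))
  invisible(x)
}

#' Voxel-wise Z-score map
#'
#' `z = (NDB mean - subject counts) / NDB SD` on the brain mask and 0
#' outside; positive Z flags a count decrease relative to the normal cohort.
#' The subject must already be preprocessed with the NDB's smoothing and
#' normalization (see [preprocess_subject()]).
#'
#' @param subject A preprocessed [subject_volume].
#' @param ndb An [ndb].
#' @return An object of class `zscore_map` with fields `z`, `brain_mask`,
#'   `subject_id`, `ndb_camera`, `sign_convention`.
#' @export
zscore_map <- function(subject, ndb) {
  stopifnot(inherits(subject, "subject_volume"), inherits(ndb, "ndb"))
  if (!identical(dim(subject$counts), dim(ndb$mean))) stop("grid mismatch")
  z <- array(0, dim(ndb$mean))
  m <- ndb$brain_mask
  z[m] <- (ndb$mean[m] - subject$counts[m]) / ndb$sd[m]
  structure(
    list(z = z, brain_mask = m, subject_id = subject$subject_id,
         ndb_camera = ndb$camera_id, sign_convention = "positive_decrease"),
    class = "zscore_map")
}

#' @export
print.zscore_map <- function(x, ...) {
  zv <- x$z[x$brain_mask]
  cat(sprintf(
    "<zscore_map '%s' vs %s NDB> mean %.3f, range %.2f..%.2f; %.2f%% with z >= 2\n",
    x$subject_id, x$ndb_camera, mean(zv), min(zv), max(zv),
    100 * mean(zv >= 2)))
  invisible(x)
}

#' Display threshold for a Z map
#'
#' Sets `z` values with `|z| < z_min` to zero — the usual noise floor
#' applied before display (1.5 in the reference protocol).
#'
#' @param zmap A [zscore_map].
#' @param z_min Minimum displayed |Z|.
#' @return A thresholded [zscore_map].
#' @export
threshold_zmap <- function(zmap, z_min = 1.5) {
  stopifnot(inherits(zmap, "zscore_map"))
  zmap$z[abs(zmap$z) < z_min] <- 0
  zmap$z_min <- z_min
  zmap
}

#' Orthogonal maximum-|Z| projections
#'
#' Simple three-view maximum-intensity projection of a Z map, plumbing for
#' quick visual checks.
#'
#' @param x A [zscore_map].
#' @param ... Passed to [graphics::image()].
#' @export
plot.zscore_map <- function(x, ...) {
  a <- abs(x$z)
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(apply(a, c(1, 2), max), axes = FALSE, main = "axial MIP", ...)
  graphics::image(apply(a, c(1, 3), max), axes = FALSE, main = "coronal MIP", ...)
  graphics::image(apply(a, c(2, 3), max), axes = FALSE, main = "sagittal MIP", ...)
  invisible(x)
}
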