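# Digital phantoms and synthetic subject cohorts.
#
# All generators emit a `digital_phantom`: paired activity (arbitrary
# activity units per voxel) and attenuation (1/cm) grids plus an integer
# tissue label grid (0 background, 1 gray matter, 2 white matter, 3 skull,
# 4 uniform pool fill) on a common aligned grid. Anatomical standardization
# is replaced by construction-time alignment: every phantom and subject lives
# on the same grid, so no registration step exists downstream.

LABEL_BG    <- 0L
LABEL_GRAY  <- 1L
LABEL_WHITE <- 2L
LABEL_SKULL <- 3L
LABEL_POOL  <- 4L

#' Construct a digital phantom
#'
#' Low-level constructor; the `make_*` generators are the usual entry points.
#'
#' @param activity 3-D non-negative array, activity per voxel (arbitrary
#'   units).
#' @param attenuation 3-D non-negative array, linear attenuation coefficient
#'   in 1/cm.
#' @param labels 3-D integer array of tissue labels (0 background, 1 gray,
#'   2 white, 3 skull, 4 pool).
#' @param voxel_size_mm Voxel size in mm (scalar or length 3).
#' @param name Text identifier.
#' @return An object of class `digital_phantom`.
#' @export
digital_phantom <- function(activity, attenuation, labels, voxel_size_mm,
                            name = "phantom") {
  if (!identical(dim(activity), dim(attenuation)) ||
      !identical(dim(activity), dim(labels)))
    stop("activity, attenuation and labels must share one shape")
  if (any(!is.finite(activity)) || any(activity < 0))
    stop("activity must be finite and non-negative")
  if (any(attenuation < 0)) stop("attenuation must be non-negative")
  if (any(activity[labels == LABEL_BG] != 0))
    stop("activity must be zero on background voxels")
  if (any(attenuation[labels == LABEL_BG] != 0))
    stop("attenuation must be zero on background voxels")
  structure(
    list(activity = activity, attenuation = attenuation,
         labels = labels, voxel_size_mm = check_voxel(voxel_size_mm),
         name = name),
    class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("<digital_phantom '%s'> %dx%dx%d @ %s mm\n", x$name,
              d[1], d[2], d[3],
              paste(format(x$voxel_size_mm), collapse = "x")))
  n <- sum(x$labels != LABEL_BG)
  cat(sprintf("  support: %d voxels (%.1f%%); total activity %.4g\n",
              n, 100 * n / prod(d), sum(x$activity)))
  tab <- table(factor(x$labels[x$labels != 0], levels = 1:4,
                      labels = c("gray", "white", "skull", "pool")))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# Shared helper: laminated (Hoffman-style) label field inside the standard
# ellipsoidal brain support. Alternating gray/white axial slabs
# `lamina_voxels` thick mimic the slice-plate construction of the physical
# phantom; a central white core keeps a contiguous deep white compartment.
#' @keywords internal
hoffman_labels <- function(shape, voxel_size_mm, lamina_voxels = 2L,
                           core_frac = 0.32) {
  shape <- check_shape(shape)
  rho2 <- ellipsoid_rho2(shape, voxel_size_mm)
  support <- rho2 <= 1
  core <- rho2 <= core_frac^2
  zi <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape)
  gray_slab <- (floor((zi - 1) / lamina_voxels) %% 2L) == 0L
  labels <- array(LABEL_BG, shape)
  labels[support] <- LABEL_WHITE
  labels[support & gray_slab & !core] <- LABEL_GRAY
  labels
}

#' Hoffman-style layered gray/white brain phantom
#'
#' Ellipsoidal brain support filled with interleaved gray/white axial laminae
#' (mimicking the stacked slice plates of the physical phantom) around a
#' central white core. Gray-matter voxels carry `gm_wm_ratio` times the
#' white-matter activity; attenuation is uniform soft tissue inside the
#' support and there is no skull compartment.
#'
#' @param shape Grid dimensions (three integers, each >= 32).
#' @param voxel_size_mm Voxel size in mm.
#' @param gm_wm_ratio Gray:white activity ratio (> 0; 4 is the conventional
#'   fill contrast of the physical phantom).
#' @param fill White-matter activity level (arbitrary units per voxel; the
#'   physical phantoms were filled at 0.3 MBq/ml).
#' @param mu_soft Soft-tissue linear attenuation coefficient, 1/cm.
#' @param lamina_voxels Lamina thickness in voxels.
#' @param seed Unused; accepted for interface uniformity — the geometry is
#'   deterministic.
#' @return A [digital_phantom].
#' @export
make_hoffman_like <- function(shape = c(64, 64, 64),
                              voxel_size_mm = c(3.5, 3.5, 3.5),
                              gm_wm_ratio = 4, fill = 0.3, mu_soft = 0.1,
                              lamina_voxels = 2L, seed = NULL) {
  shape <- check_shape(shape)
  if (any(shape < 32)) stop("`shape` must be at least 32 along every axis")
  if (!is.finite(gm_wm_ratio) || gm_wm_ratio <= 0)
    stop("`gm_wm_ratio` must be positive")
  labels <- hoffman_labels(shape, voxel_size_mm, lamina_voxels)
  activity <- array(0, shape)
  activity[labels == LABEL_WHITE] <- fill
  activity[labels == LABEL_GRAY] <- fill * gm_wm_ratio
  attenuation <- array(0, shape)
  attenuation[labels != LABEL_BG] <- mu_soft
  digital_phantom(activity, attenuation, labels, voxel_size_mm,
                  name = "hoffman")
}

#' Skull-attenuated gray-matter brain phantom
#'
#' Same brain support and laminae as [make_hoffman_like()], plus a closed
#' skull shell of bone-equivalent attenuation (`skull_mu`) with zero
#' activity. By default only gray matter carries tracer (`gm_only = TRUE`),
#' as in the physical anatomical phantom whose gray-matter compartment alone
#' can hold radionuclide.
#'
#' @inheritParams make_hoffman_like
#' @param gm_only If `TRUE` (default) white-matter voxels carry no activity.
#' @param skull_mu Skull linear attenuation coefficient, 1/cm; must exceed
#'   `mu_soft`.
#' @param shell_scale Outer scale of the skull ellipsoid relative to the
#'   brain support.
#' @return A [digital_phantom].
#' @export
make_3dbrain_like <- function(shape = c(64, 64, 64),
                              voxel_size_mm = c(3.5, 3.5, 3.5),
                              gm_only = TRUE, skull_mu = 0.15,
                              gm_wm_ratio = 4, fill = 0.3, mu_soft = 0.1,
                              lamina_voxels = 2L, shell_scale = 1.10,
                              seed = NULL) {
  if (!is.finite(skull_mu) || skull_mu <= mu_soft)
    stop("`skull_mu` must exceed the soft-tissue attenuation `mu_soft`")
  base <- make_hoffman_like(shape, voxel_size_mm, gm_wm_ratio, fill, mu_soft,
                            lamina_voxels)
  rho2 <- ellipsoid_rho2(dim(base$labels), voxel_size_mm)
  shell <- rho2 > 1 & rho2 <= shell_scale^2
  labels <- base$labels
  labels[shell] <- LABEL_SKULL
  activity <- base$activity
  if (gm_only) activity[labels == LABEL_WHITE] <- 0
  attenuation <- base$attenuation
  attenuation[shell] <- skull_mu
  digital_phantom(activity, attenuation, labels, voxel_size_mm,
                  name = "brain3d")
}

#' Uniform pool phantom
#'
#' Uniform activity with no internal brain structure; the simplest
#' compensation object. With `shape_kind = "brain"` (default) the fill
#' occupies the same outer support as the Hoffman-style phantom. With
#' `shape_kind = "cylinder"` it occupies a cylinder slightly larger than
#' the brain support — the physical pool is the phantom's container with
#' the brain-slice plates removed, so its outline (and hence its
#' attenuation geometry) is that of the cylinder, not of a head.
#'
#' @inheritParams make_hoffman_like
#' @param shape_kind `"brain"` or `"cylinder"` (see Details).
#' @return A [digital_phantom].
#' @export
make_pool <- function(shape = c(64, 64, 64),
                      voxel_size_mm = c(3.5, 3.5, 3.5),
                      fill = 0.3, mu_soft = 0.1,
                      shape_kind = c("brain", "cylinder")) {
  shape_kind <- match.arg(shape_kind)
  shape <- check_shape(shape)
  if (any(shape < 32)) stop("`shape` must be at least 32 along every axis")
  if (shape_kind == "brain") {
    support <- ellipsoid_rho2(shape, voxel_size_mm) <= 1
  } else {
    v <- check_voxel(voxel_size_mm)
    half <- shape * v / 2
    r_cyl <- 1.12 * max(0.72 * half[1], 0.85 * half[2])
    h_cyl <- 1.25 * 0.62 * half[3]
    co <- coord_arrays(shape, v)
    support <- (co$x^2 + co$y^2) <= r_cyl^2 & abs(co$z) <= h_cyl
  }
  labels <- array(LABEL_BG, shape)
  labels[support] <- LABEL_POOL
  activity <- array(0, shape)
  activity[support] <- fill
  attenuation <- array(0, shape)
  attenuation[support] <- mu_soft
  digital_phantom(activity, attenuation, labels, voxel_size_mm, name = "pool")
}

#' Smooth cortical-shell brain (normal-subject anatomy base)
#'
#' A brain-like activity distribution used as the anatomy of simulated
#' normal subjects: a hot cortical gray-matter shell and deep gray nuclei
#' over a white-matter interior, on the standard ellipsoidal support. Unlike
#' the plate-phantom geometry of [make_hoffman_like()], the gray matter
#' follows the brain surface — the structural mismatch between plate
#' phantoms and real brains is exactly what the harmonization study probes,
#' so subjects and phantoms must not share fine structure.
#'
#' @inheritParams make_hoffman_like
#' @param shell_frac Fractional radial thickness of the cortical shell.
#' @param core_frac Fractional radius of the deep gray compartment.
#' @return A [digital_phantom].
#' @export
make_brain_like <- function(shape = c(64, 64, 64),
                            voxel_size_mm = c(3.5, 3.5, 3.5),
                            gm_wm_ratio = 4, fill = 0.3, mu_soft = 0.1,
                            shell_frac = 0.18, core_frac = 0.28,
                            seed = NULL) {
  shape <- check_shape(shape)
  if (any(shape < 32)) stop("`shape` must be at least 32 along every axis")
  if (!is.finite(gm_wm_ratio) || gm_wm_ratio <= 0)
    stop("`gm_wm_ratio` must be positive")
  rho2 <- ellipsoid_rho2(shape, voxel_size_mm)
  rho <- sqrt(rho2)
  support <- rho <= 1
  gray <- support & (rho > 1 - shell_frac | rho <= core_frac)
  labels <- array(LABEL_BG, shape)
  labels[support] <- LABEL_WHITE
  labels[gray] <- LABEL_GRAY
  activity <- array(0, shape)
  activity[labels == LABEL_WHITE] <- fill
  activity[labels == LABEL_GRAY] <- fill * gm_wm_ratio
  attenuation <- array(0, shape)
  attenuation[support] <- mu_soft
  digital_phantom(activity, attenuation, labels, voxel_size_mm,
                  name = "brainlike")
}

#' Generate a cohort of synthetic normal subjects
#'
#' Each subject's activity is the base phantom's activity times a global
#' log-normal scalar (coefficient of variation `between_subject_cv`) and a
#' smooth positive multiplicative field of unit mean (log-Gaussian, local
#' coefficient of variation `local_cv`, correlation length
#' `field_smoothness_mm`). The multiplicative log-normal construction keeps
#' activity strictly positive and yields smooth, brain-like inter-subject
#' structure. Attenuation and labels are copied from the base. Deterministic
#' under a fixed seed.
#'
#' @param base A [digital_phantom] giving the shared anatomy.
#' @param n Number of subjects (>= 2; a normal database needs an SD).
#' @param between_subject_cv Coefficient of variation of the global scalar,
#'   in `[0, 0.5)`.
#' @param local_cv Coefficient of variation of the smooth local field.
#' @param field_smoothness_mm Correlation length (FWHM) of the local field,
#'   mm.
#' @param seed Integer seed.
#' @return A list of `n` [digital_phantom] objects with per-subject names.
#' @export
make_subject_cohort <- function(base, n, between_subject_cv = 0.08,
                                local_cv = 0.05, field_smoothness_mm = 20,
                                seed = 1L) {
  stopifnot(inherits(base, "digital_phantom"))
  if (n < 2) stop("`n` must be at least 2 (an NDB needs an SD)")
  if (between_subject_cv < 0 || between_subject_cv >= 0.5)
    stop("`between_subject_cv` must lie in [0, 0.5)")
  if (local_cv < 0) stop("`local_cv` must be non-negative")
  set.seed(seed)
  sg <- sqrt(log(1 + between_subject_cv^2))
  sl <- sqrt(log(1 + local_cv^2))
  lapply(seq_len(n), function(i) {
    g <- exp(stats::rnorm(1, 0, sg) - sg^2 / 2)
    act <- base$activity * g
    if (local_cv > 0) {
      w <- array(stats::rnorm(length(base$activity)), dim(base$activity))
      w <- gaussian_smooth(w, field_smoothness_mm, base$voxel_size_mm)
      w <- (w - mean(w)) / stats::sd(w)
      act <- act * exp(sl * w - sl^2 / 2)
    }
    out <- base
    out$activity <- act
    out$name <- sprintf("%s_subj%02d", base$name, i)
    out
  })
}

#' Apply a simulated hypoperfusion lesion
#'
#' Multiplies activity (for a [digital_phantom]) or counts (for a
#' [subject_volume]) by `1 - reduction_fraction` inside `voi_mask`, leaving
#' voxels outside the mask untouched; this is the digital disease
#' simulation used to probe the correction pipeline (20% reduction inside
#' the disease VOI in the reference protocol).
#'
#' @param subject A [digital_phantom] or [subject_volume].
#' @param voi_mask 3-D logical (or 0/1) array on the same grid.
#' @param reduction_fraction Fractional count reduction in `(0, 1)`.
#' @return A new object of the same class; the input is not modified.
#' @export
apply_ad_lesion <- function(subject, voi_mask, reduction_fraction = 0.2) {
  if (reduction_fraction <= 0 || reduction_fraction >= 1)
    stop("`reduction_fraction` must lie strictly between 0 and 1")
  field <- if (inherits(subject, "digital_phantom")) "activity" else "counts"
  if (!identical(dim(subject[[field]]), dim(voi_mask)))
    stop("mask shape does not match the subject grid")
  mask <- voi_mask > 0
  if (!any(mask)) {
    warning("empty lesion mask: returning the input unchanged")
    return(subject)
  }
  out <- subject
  out[[field]][mask] <- out[[field]][mask] * (1 - reduction_fraction)
  out
}

#' Construct a subject volume
#'
#' Container for one reconstructed SPECT volume: counts per voxel plus
#' acquisition provenance.
#'
#' @param counts 3-D non-negative array of reconstructed counts.
#' @param voxel_size_mm Voxel size in mm.
#' @param subject_id,camera_id Text identifiers.
#' @param attenuation_corrected Logical flag.
#' @param meta Free-form provenance list (seed, generation parameters, ...).
#' @return An object of class `subject_volume`.
#' @export
subject_volume <- function(counts, voxel_size_mm, subject_id = "subject",
                           camera_id = "camera",
                           attenuation_corrected = NA, meta = list()) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  structure(
    list(counts = counts, voxel_size_mm = check_voxel(voxel_size_mm),
         subject_id = subject_id, camera_id = camera_id,
         attenuation_corrected = attenuation_corrected, meta = meta),
    class = "subject_volume")
}

#' @export
print.subject_volume <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<subject_volume '%s'> camera %s, AC%s, %dx%dx%d, total counts %.4g\n",
    x$subject_id, x$camera_id,
    if (isTRUE(x$attenuation_corrected)) "+" else "-",
    d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Mid-slice display of a phantom
#'
#' @param x A [digital_phantom].
#' @param what `"activity"`, `"attenuation"` or `"labels"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.digital_phantom <- function(x, what = "activity", ...) {
  a <- x[[what]]
  d <- dim(a)
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(a[, , ceiling(d[3] / 2)], axes = FALSE, main = "axial", ...)
  graphics::image(a[, ceiling(d[2] / 2), ], axes = FALSE, main = "coronal", ...)
  graphics::image(a[ceiling(d[1] / 2), , ], axes = FALSE, main = "sagittal", ...)
  invisible(x)
}
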