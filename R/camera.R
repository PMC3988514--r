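# Reconstruction-domain gamma-camera simulator.
#
# Acquisition is simulated directly in the reconstructed-image domain:
# activity x attenuation factor x sensitivity -> PSF blur -> count scaling
# and Poisson sampling -> Butterworth post-filter -> optional first-order
# Chang attenuation correction. Projection-space physics (FBP, scatter,
# energy resolution) is deliberately out of scope: every evaluated quantity
# in the harmonization study operates on reconstructed, aligned volumes, so
# a projection model would add cost without touching any end point.

#' Parameterized gamma camera
#'
#' Bundles the simulator parameters of one camera: PSF width, Butterworth
#' post-filter, a smooth radial sensitivity gradient (standing in for
#' detector/collimator differences), the Chang coefficient used when
#' attenuation correction is on, and the expected total detected counts.
#'
#' @param camera_id Text identifier.
#' @param psf_fwhm_mm Gaussian PSF full width at half maximum, mm (> 0, or 0
#'   to disable blurring).
#' @param butterworth_cutoff Post-filter cut-off, in the unit given by
#'   `cutoff_unit`.
#' @param cutoff_unit `"cyc_per_cm"` (cycles/cm) or `"nyquist"` (fraction of
#'   the grid Nyquist frequency); clinical consoles print either, so the
#'   conversion from voxel size is done explicitly at filter time.
#' @param butterworth_order Filter order (positive integer).
#' @param sensitivity_gradient Amplitude `g` of the radial sensitivity field
#'   `1 + g * (2 (r/rmax)^2 - 1)` (centre `1-g`, periphery `1+g`), rescaled
#'   to unit mean over the object support. Zero disables it.
#' @param chang_mu Assumed uniform attenuation coefficient for Chang
#'   correction, 1/cm.
#' @param count_budget Expected total detected counts per acquisition;
#'   `Inf` means a noise-free acquisition (no scaling, no Poisson sampling).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(camera_id, psf_fwhm_mm = 8,
                         butterworth_cutoff = 0.45,
                         cutoff_unit = c("nyquist", "cyc_per_cm"),
                         butterworth_order = 8, sensitivity_gradient = 0,
                         chang_mu = 0.1, count_budget = 5e6) {
  cutoff_unit <- match.arg(cutoff_unit)
  if (psf_fwhm_mm < 0) stop("`psf_fwhm_mm` must be non-negative")
  if (butterworth_cutoff <= 0) stop("`butterworth_cutoff` must be positive")
  if (butterworth_order < 1) stop("`butterworth_order` must be >= 1")
  if (count_budget <= 0) stop("`count_budget` must be positive")
  structure(
    list(camera_id = camera_id, psf_fwhm_mm = psf_fwhm_mm,
         butterworth_cutoff = butterworth_cutoff, cutoff_unit = cutoff_unit,
         butterworth_order = as.integer(butterworth_order),
         sensitivity_gradient = sensitivity_gradient,
         chang_mu = chang_mu, count_budget = count_budget),
    class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model '%s'> PSF %.4g mm, Butterworth %.4g %s (order %d),\n",
    x$camera_id, x$psf_fwhm_mm, x$butterworth_cutoff,
    if (x$cutoff_unit == "nyquist") "x Nyquist" else "cycles/cm",
    x$butterworth_order))
  cat(sprintf("  sensitivity gradient %+.2g, Chang mu %.3g /cm, budget %s\n",
              x$sensitivity_gradient, x$chang_mu,
              format(x$count_budget)))
  invisible(x)
}

#' Default two-camera configuration
#'
#' The reference camera ("ecam") and target camera ("irix") differ in PSF
#' width (8 vs 10 mm), Butterworth cut-off stated in the unit each console
#' uses (0.45 x Nyquist vs 0.75 cycles/cm — the clinical settings chosen so
#' the two reconstructions have near-equal resolution) and a +/-5% radial
#' sensitivity gradient on the target camera reproducing its central-count
#' decrease / marginal increase.
#'
#' @param count_budget Expected counts per acquisition for both cameras.
#' @return Named list with elements `reference` and `target`.
#' @export
default_cameras <- function(count_budget = 5e6) {
  list(
    reference = camera_model("ecam", psf_fwhm_mm = 8,
                             butterworth_cutoff = 0.45,
                             cutoff_unit = "nyquist",
                             sensitivity_gradient = 0,
                             count_budget = count_budget),
    target = camera_model("irix", psf_fwhm_mm = 10,
                          butterworth_cutoff = 0.75,
                          cutoff_unit = "cyc_per_cm",
                          sensitivity_gradient = 0.05,
                          count_budget = count_budget))
}

#' The six axis-aligned unit directions
#'
#' Default direction set for attenuation path integrals (a cheap Chang-style
#' mean over opposed rays).
#'
#' @return A list of six unit 3-vectors.
#' @export
axis_directions <- function() {
  list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
       c(0, 0, 1), c(0, 0, -1))
}

# Path integral of mu (1/cm) from every voxel centre to the volume boundary
# along one direction. Axis-aligned rays are integrated exactly over the
# piecewise-constant mu grid (half of the emitting voxel plus all downstream
# voxels); oblique rays fall back to half-voxel-step ray marching with
# nearest-voxel sampling.
#' @keywords internal
path_integral_mm <- function(mu, voxel_size_mm, direction) {
  d <- direction / sqrt(sum(direction^2))
  axis <- which(abs(d) > 1e-12)
  if (length(axis) == 1L && abs(abs(d[axis]) - 1) < 1e-12) {
    k <- axis
    forward <- d[k] > 0
    dd <- dim(mu)
    perm <- c(k, setdiff(1:3, k))
    m <- matrix(aperm(mu, perm), nrow = dd[k])
    if (forward) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    cs <- apply(m, 2, cumsum)           # sum of mu from boundary up to voxel
    if (forward) cs <- cs[rev(seq_len(nrow(cs))), , drop = FALSE]
    m0 <- if (forward) m[rev(seq_len(nrow(m))), , drop = FALSE] else m
    path <- cs - 0.5 * m0               # half of the emitting voxel
    out <- array(path, dd[perm])
    return(aperm(out, order(perm)) * voxel_size_mm[k])
  }
  # oblique ray: half-voxel stepping, nearest-voxel sampling
  step_mm <- 0.5 * min(voxel_size_mm)
  extent <- sqrt(sum((dim(mu) * voxel_size_mm)^2))
  nsteps <- ceiling(extent / step_mm)
  acc <- 0.5 * mu
  for (t in seq_len(nsteps)) {
    off <- round(t * step_mm * d / voxel_size_mm)
    if (all(abs(off) >= dim(mu))) break
    acc <- acc + shift_array(mu, off)
  }
  acc * step_mm
}

#' Mean attenuation survival factor
#'
#' For each voxel, the mean over the direction set of `exp(-integral mu dl)`
#' along the ray from the voxel to the volume boundary, with `mu` in 1/cm
#' and path lengths from the voxel size. Values lie in `(0, 1]`.
#'
#' @param phantom A [digital_phantom] supplying the attenuation grid, or a
#'   bare 3-D array of attenuation coefficients (then `voxel_size_mm` is
#'   required).
#' @param directions List of 3-vectors (need not be unit length); defaults
#'   to the six axis-aligned rays.
#' @param voxel_size_mm Voxel size when `phantom` is a bare array.
#' @return 3-D array of survival factors.
#' @export
attenuation_factor <- function(phantom, directions = axis_directions(),
                               voxel_size_mm = NULL) {
  if (inherits(phantom, "digital_phantom")) {
    mu <- phantom$attenuation
    voxel_size_mm <- phantom$voxel_size_mm
  } else {
    mu <- phantom
    if (is.null(voxel_size_mm)) stop("`voxel_size_mm` is required")
    voxel_size_mm <- check_voxel(voxel_size_mm)
  }
  if (length(directions) == 0) stop("`directions` must be non-empty")
  if (any(mu < 0)) stop("attenuation must be non-negative")
  acc <- array(0, dim(mu))
  for (d in directions)
    acc <- acc + exp(-path_integral_mm(mu, voxel_size_mm, d) / 10)
  acc / length(directions)
}

#' First-order Chang attenuation correction
#'
#' Divides a reconstructed image voxel-wise by the mean attenuation survival
#' factor computed with a uniform assumed coefficient `chang_mu` over the
#' object support — the classical one-step reconstruction-domain correction.
#'
#' @param image 3-D array or [subject_volume].
#' @param phantom A [digital_phantom] supplying support (labels > 0) and
#'   voxel size. Ignored when `factor` is supplied.
#' @param chang_mu Assumed uniform attenuation coefficient, 1/cm.
#' @param directions Direction set, as in [attenuation_factor()].
#' @param factor Optional precomputed correction factor array (as returned
#'   by [attenuation_factor()] on the uniform `chang_mu` map); lets callers
#'   amortize the path integrals over many acquisitions.
#' @param eps Division clamp: factors below `eps` are raised to `eps`.
#' @return Corrected image, same type as `image`.
#' @export
chang_correction <- function(image, phantom = NULL, chang_mu = 0.1,
                             directions = axis_directions(), factor = NULL,
                             eps = 1e-3) {
  if (is.null(factor)) {
    if (is.null(phantom)) stop("supply either `phantom` or `factor`")
    mu <- array(0, dim(phantom$labels))
    mu[phantom$labels > 0] <- chang_mu
    factor <- attenuation_factor(mu, directions, phantom$voxel_size_mm)
  }
  fac <- pmax(factor, eps)
  if (inherits(image, "subject_volume")) {
    if (!identical(dim(image$counts), dim(fac))) stop("grid mismatch")
    image$counts <- image$counts / fac
    image$attenuation_corrected <- TRUE
    return(image)
  }
  if (!identical(dim(image), dim(fac))) stop("grid mismatch")
  image / fac
}

#' Butterworth low-pass post-filter
#'
#' Frequency-domain multiplication by the isotropic 3-D Butterworth
#' magnitude response `1 / sqrt(1 + (f/fc)^(2n))`. The zero-frequency gain
#' is exactly 1, so total counts are preserved up to floating error.
#'
#' @param image 3-D array.
#' @param cutoff Cut-off frequency, in `cutoff_unit`.
#' @param order Filter order `n`.
#' @param voxel_size_mm Voxel size, mm.
#' @param cutoff_unit `"cyc_per_cm"` or `"nyquist"` (fraction of the
#'   smallest grid Nyquist frequency).
#' @return Filtered 3-D array.
#' @export
butterworth_filter <- function(image, cutoff, order = 8, voxel_size_mm,
                               cutoff_unit = c("cyc_per_cm", "nyquist")) {
  cutoff_unit <- match.arg(cutoff_unit)
  if (cutoff <= 0) stop("`cutoff` must be positive")
  v <- check_voxel(voxel_size_mm)
  nyq <- 10 / (2 * max(v))              # cycles/cm of the coarsest axis
  fc <- if (cutoff_unit == "nyquist") cutoff * nyq else cutoff
  if (fc > 10 / (2 * min(v)))
    warning("cut-off above the grid Nyquist frequency: filtering is mild")
  f <- sqrt(freq_sq_grid(dim(image), v)) * 10   # cycles/cm
  H <- 1 / sqrt(1 + (f / fc)^(2 * order))
  apply_transfer(image, H)
}

# Radial sensitivity field of a camera over a phantom's support, unit mean
# on the support.
#' @keywords internal
sensitivity_field <- function(camera, phantom) {
  g <- camera$sensitivity_gradient
  if (g == 0) return(NULL)
  co <- coord_arrays(dim(phantom$labels), phantom$voxel_size_mm)
  r2 <- co$x^2 + co$y^2 + co$z^2
  support <- phantom$labels > 0
  r2max <- max(r2[support])
  s <- 1 + g * (2 * r2 / r2max - 1)
  s / mean(s[support])
}

#' Simulate one SPECT acquisition
#'
#' Full reconstruction-domain chain: activity x attenuation survival factor
#' x sensitivity field, Gaussian PSF blur, scaling of the total to the
#' camera's count budget followed by Poisson sampling (both skipped for an
#' infinite budget), Butterworth post-filtering, and — when
#' `attenuation_correction` is `TRUE` — first-order Chang correction with
#' the camera's `chang_mu` over the phantom support.
#'
#' @param phantom A [digital_phantom].
#' @param camera A [camera_model].
#' @param attenuation_correction Apply Chang correction (`TRUE`) or emit
#'   AC- data (`FALSE`).
#' @param seed Integer seed for the stochastic stages (session field and
#'   Poisson draw).
#' @param directions Direction set for attenuation and Chang factors.
#' @param att,chang_fac Optional precomputed attenuation survival and Chang
#'   correction factor arrays for this phantom geometry (performance).
#' @param session_cv Coefficient of variation of a smooth multiplicative
#'   per-acquisition field modelling scan-to-scan (repositioning /
#'   detector-state) variability between separate acquisition sessions;
#'   0 (default) disables it.
#' @param session_smoothness_mm Correlation length (FWHM) of the session
#'   field, mm.
#' @param subject_id Identifier recorded on the output.
#' @return A [subject_volume] with provenance in `$meta`.
#' @export
acquire <- function(phantom, camera, attenuation_correction = TRUE,
                    seed = NULL, directions = axis_directions(),
                    att = NULL, chang_fac = NULL, session_cv = 0,
                    session_smoothness_mm = 30,
                    subject_id = phantom$name) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(camera, "camera_model"))
  if (!is.null(seed)) set.seed(seed)
  img <- phantom$activity
  if (session_cv > 0) {
    sl <- sqrt(log(1 + session_cv^2))
    w <- array(stats::rnorm(length(img)), dim(img))
    w <- gaussian_smooth(w, session_smoothness_mm, phantom$voxel_size_mm)
    w <- (w - mean(w)) / stats::sd(w)
    img <- img * exp(sl * w - sl^2 / 2)
  }
  if (any(phantom$attenuation > 0)) {
    if (is.null(att)) att <- attenuation_factor(phantom, directions)
    img <- img * att
  }
  sens <- sensitivity_field(camera, phantom)
  if (!is.null(sens)) img <- img * sens
  if (camera$psf_fwhm_mm > 0)
    img <- gaussian_smooth(img, camera$psf_fwhm_mm, phantom$voxel_size_mm)
  img[img < 0] <- 0                      # clip FFT ringing before sampling
  noisy <- is.finite(camera$count_budget)
  if (noisy) {
    img <- img * (camera$count_budget / sum(img))
    img <- array(stats::rpois(length(img), img), dim(img))
  }
  img <- butterworth_filter(img, camera$butterworth_cutoff,
                            camera$butterworth_order,
                            phantom$voxel_size_mm, camera$cutoff_unit)
  img[img < 0] <- 0                      # filter undershoot
  if (attenuation_correction) {
    if (is.null(chang_fac)) {
      mu <- array(0, dim(phantom$labels))
      mu[phantom$labels > 0] <- camera$chang_mu
      chang_fac <- attenuation_factor(mu, directions,
                                      phantom$voxel_size_mm)
    }
    img <- chang_correction(img, factor = chang_fac)
  }
  subject_volume(img, phantom$voxel_size_mm, subject_id = subject_id,
                 camera_id = camera$camera_id,
                 attenuation_corrected = attenuation_correction,
                 meta = list(seed = seed, phantom = phantom$name,
                             count_budget = camera$count_budget,
                             noise = noisy, session_cv = session_cv))
}
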