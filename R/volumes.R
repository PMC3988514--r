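# Grid geometry and frequency-domain helpers shared by the simulators.
# All volumes are plain 3-D numeric arrays on one common grid; physical voxel
# size is carried alongside in mm, attenuation coefficients in 1/cm.

#' @keywords internal
check_shape <- function(shape) {
  if (length(shape) != 3L || any(shape < 1) || any(shape != round(shape)))
    stop("`shape` must be three positive integers")
  as.integer(shape)
}

#' @keywords internal
check_voxel <- function(voxel_size_mm) {
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three positive values (mm)")
  as.numeric(voxel_size_mm)
}

# DFT sample frequencies (cycles per unit of `d`), fftshift-free ordering.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  k <- seq_len(n) - 1L
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k / (n * d)
}

# Axis coordinates in mm, centred on the grid centre.
#' @keywords internal
axis_coords <- function(n, d) (seq_len(n) - (n + 1) / 2) * d

# Coordinate arrays (mm, grid-centred) for a given shape.
#' @keywords internal
coord_arrays <- function(shape, voxel_size_mm) {
  shape <- check_shape(shape)
  v <- check_voxel(voxel_size_mm)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  list(
    x = array(axis_coords(nx, v[1]), shape),
    y = array(rep(axis_coords(ny, v[2]), each = nx), shape),
    z = array(rep(axis_coords(nz, v[3]), each = nx * ny), shape)
  )
}

# Squared radial spatial frequency |f|^2 in cycles^2/mm^2 for an FFT grid.
#' @keywords internal
freq_sq_grid <- function(shape, voxel_size_mm) {
  shape <- check_shape(shape)
  v <- check_voxel(voxel_size_mm)
  fx2 <- fft_freq(shape[1], v[1])^2
  fy2 <- fft_freq(shape[2], v[2])^2
  fz2 <- fft_freq(shape[3], v[3])^2
  outer(outer(fx2, fy2, "+"), fz2, "+")
}

# Apply a real frequency-domain transfer function to a real volume.
#' @keywords internal
apply_transfer <- function(x, H) {
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / length(x)
}

#' Gaussian smoothing of a 3-D volume
#'
#' Isotropic Gaussian filter specified by its full width at half maximum in
#' mm, implemented in the frequency domain (periodic boundary; the brain
#' support is assumed to sit away from the grid edges, as it does for all
#' generated phantoms). The zero-frequency gain is exactly 1, so total counts
#' are preserved up to floating error.
#'
#' @param x 3-D numeric array.
#' @param fwhm_mm Full width at half maximum of the Gaussian kernel, mm.
#'   Zero or negative returns `x` unchanged.
#' @param voxel_size_mm Voxel size, mm (scalar or length 3).
#' @return A 3-D array of the same shape.
#' @export
gaussian_smooth <- function(x, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm <= 0) return(x)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  F2 <- freq_sq_grid(dim(x), voxel_size_mm)
  apply_transfer(x, exp(-2 * pi^2 * sigma^2 * F2))
}

# Ellipsoidal squared "radius" rho^2 with semi-axes given as fractions of the
# grid half-extent; rho <= 1 is the default brain support.
#' @keywords internal
ellipsoid_rho2 <- function(shape, voxel_size_mm,
                           semi_frac = c(0.72, 0.85, 0.62)) {
  v <- check_voxel(voxel_size_mm)
  half <- check_shape(shape) * v / 2
  semi <- semi_frac * half
  co <- coord_arrays(shape, v)
  (co$x / semi[1])^2 + (co$y / semi[2])^2 + (co$z / semi[3])^2
}

# Shift an array by integer voxel offsets, filling with zeros.
#' @keywords internal
shift_array <- function(a, offset) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- offset[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) { src[[k]] <- (1 + o):d[k]; dst[[k]] <- 1:(d[k] - o) }
    else        { src[[k]] <- 1:(d[k] + o); dst[[k]] <- (1 - o):d[k] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
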