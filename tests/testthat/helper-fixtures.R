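# Shared fixtures: small grids keep the suite fast; every fixture is built
# in code at test time.

SMALL <- c(32L, 32L, 32L)
VOX <- c(3.5, 3.5, 3.5)

# a camera whose chain is effectively transparent apart from the stages a
# test switches on (no PSF, very high cut-off, unit sensitivity, noise-free)
ideal_camera <- function(id = "ideal", count_budget = Inf, ...) {
  camera_model(id, psf_fwhm_mm = 0, butterworth_cutoff = 100,
               cutoff_unit = "cyc_per_cm", sensitivity_gradient = 0,
               count_budget = count_budget, ...)
}

# acquire() warns (by design) when the cut-off exceeds Nyquist; the ideal
# camera does that on purpose
acquire_quiet <- function(...) suppressWarnings(acquire(...))

# bare Z-score map for index/evaluation tests
make_zmap <- function(z, brain_mask, subject_id = "fixture") {
  structure(list(z = z, brain_mask = brain_mask, subject_id = subject_id,
                 ndb_camera = "fixture",
                 sign_convention = "positive_decrease"),
            class = "zscore_map")
}

# subject volumes straight from phantom activities (a noise-free,
# camera-free "acquisition" for pipeline algebra tests)
as_subjects <- function(phantoms) {
  lapply(phantoms, function(p)
    subject_volume(p$activity, p$voxel_size_mm, subject_id = p$name))
}
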