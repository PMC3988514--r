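# NIfTI-1 and plain-text persistence.
#
# Volumes travel as NIfTI-1 (via RNifti) with the voxel size in the header;
# masks as {0,1} volumes; run configurations and sidecar provenance as YAML.

#' Write a 3-D volume as NIfTI-1
#'
#' @param x 3-D array, [subject_volume] or [zscore_map] (its `z` grid).
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size for bare arrays; taken from the object
#'   otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = NULL) {
  if (inherits(x, "subject_volume")) {
    arr <- x$counts; voxel_size_mm <- x$voxel_size_mm
  } else if (inherits(x, "zscore_map")) {
    arr <- x$z
    voxel_size_mm <- voxel_size_mm %||% c(1, 1, 1)
  } else {
    arr <- x
    if (is.logical(arr)) arr <- array(as.numeric(arr), dim(arr))
    voxel_size_mm <- voxel_size_mm %||% c(1, 1, 1)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- check_voxel(voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path File path.
#' @return List with `data` (3-D array) and `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)[1:3]),
       voxel_size_mm = RNifti::pixdim(img)[1:3])
}

#' Write a digital phantom as NIfTI-1 volumes
#'
#' Writes `<prefix>_activity.nii.gz`, `<prefix>_attenuation.nii.gz` and
#' `<prefix>_labels.nii.gz`.
#'
#' @param phantom A [digital_phantom].
#' @param prefix Path prefix.
#' @return The three paths, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "digital_phantom"))
  paths <- paste0(prefix, "_", c("activity", "attenuation", "labels"),
                  ".nii.gz")
  write_volume(phantom$activity, paths[1], phantom$voxel_size_mm)
  write_volume(phantom$attenuation, paths[2], phantom$voxel_size_mm)
  write_volume(array(as.numeric(phantom$labels), dim(phantom$labels)),
               paths[3], phantom$voxel_size_mm)
  invisible(paths)
}

#' Write a compensation map as NIfTI-1 plus a YAML sidecar
#'
#' @param comp A [compensation_map].
#' @param prefix Path prefix; writes `<prefix>_ratio.nii.gz`,
#'   `<prefix>_mask.nii.gz` and `<prefix>.yaml`.
#' @return The paths, invisibly.
#' @export
write_compensation_map <- function(comp, prefix) {
  stopifnot(inherits(comp, "compensation_map"))
  paths <- c(paste0(prefix, "_ratio.nii.gz"),
             paste0(prefix, "_mask.nii.gz"),
             paste0(prefix, ".yaml"))
  write_volume(comp$ratio, paths[1], comp$voxel_size_mm)
  write_volume(comp$valid_mask, paths[2], comp$voxel_size_mm)
  yaml::write_yaml(
    list(source = comp$source, n_reference = comp$n_reference,
         n_target = comp$n_target,
         smoothing_fwhm_mm = comp$smoothing_fwhm_mm,
         reference_camera = comp$reference_camera,
         target_camera = comp$target_camera),
    paths[3])
  invisible(paths)
}

#' Read or write a run configuration
#'
#' Configurations are plain YAML; a run is reproducible from the
#' configuration (which embeds all seeds) alone.
#'
#' @param config A configuration list (see [default_config()]).
#' @param path File path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)
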