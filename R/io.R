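#' @importFrom RNifti readNifti writeNifti asNifti pixdim
NULL

nifti_write_array <- function(arr, spacing_mm, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_mm[seq_along(dim(arr))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_read_array <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing_mm = RNifti::pixdim(img))
}

#' Write / read a spin-lock series as NIfTI + JSON sidecar
#'
#' The 4-D intensity stack goes to `<prefix>.nii.gz`; the acquisition times,
#' modality and spacing go to `<prefix>.json`.  Round-trips are exact on
#' data and spacing.
#'
#' @param series a [spin_lock_series()].
#' @param prefix output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_spin_lock_series <- function(series, prefix) {
  stopifnot(inherits(series, "spin_lock_series"))
  nifti_write_array(series$signals, c(series$spacing_mm, 1),
                    paste0(prefix, ".nii.gz"))
  jsonlite::write_json(list(tsl_ms = series$tsl_ms,
                            modality_tag = series$modality_tag,
                            spacing_mm = series$spacing_mm),
                       paste0(prefix, ".json"), digits = NA)
  invisible(prefix)
}

#' @rdname write_spin_lock_series
#' @export
read_spin_lock_series <- function(prefix) {
  vol <- nifti_read_array(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (length(dim(vol$data)) != 4L)
    stop("format error: expected a 4-D NIfTI stack")
  if (dim(vol$data)[4] != length(side$tsl_ms))
    stop("format error: ", length(side$tsl_ms), " acquisition times for ",
         dim(vol$data)[4], " volumes")
  spin_lock_series(vol$data, side$tsl_ms, side$spacing_mm, side$modality_tag)
}

#' Write / read a disc segmentation as NIfTI + JSON sidecar
#'
#' @param seg a [disc_segmentation()].
#' @param prefix output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_segmentation <- function(seg, prefix) {
  stopifnot(inherits(seg, "disc_segmentation"))
  nifti_write_array(seg$labels, seg$spacing_mm, paste0(prefix, ".nii.gz"))
  jsonlite::write_json(list(spacing_mm = seg$spacing_mm,
                            axis_convention = seg$axis_convention),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(prefix) {
  vol <- nifti_read_array(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  disc_segmentation(array(as.integer(round(vol$data)), dim = dim(vol$data)),
                    side$spacing_mm, as.list(side$axis_convention))
}

#' Write a relaxation map as NIfTI volumes
#'
#' Writes `t_ms`, `s0`, `fit_r2` and `valid` volumes under
#' `<prefix>_<field>.nii.gz`.  Invalid voxels carry NaN in the parameter
#' volumes (never silent zeros).
#'
#' @param map a [fit_map()] result.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_relaxation_map <- function(map, prefix) {
  stopifnot(inherits(map, "relaxation_map"))
  for (f in c("t_ms", "s0", "fit_r2"))
    nifti_write_array(map[[f]], map$spacing_mm,
                      paste0(prefix, "_", gsub("_", "", f), ".nii.gz"))
  nifti_write_array(array(as.numeric(map$valid), dim = dim(map$valid)),
                    map$spacing_mm, paste0(prefix, "_valid.nii.gz"))
  invisible(prefix)
}

#' Pipeline run configuration
#'
#' A single structured record of every tunable the pipeline uses, written
#' alongside all outputs as the reproducibility record.
#'
#' @param tsl_ms spin-lock time grid (ms).
#' @param t_min,t_max relaxation-time clamp (ms).
#' @param noise_sigma background noise SD estimate (0 = no masking).
#' @param np_fraction central AP fraction defining the nucleus pulposus.
#' @param min_voxels minimum valid NP voxels for a usable disc mean.
#' @param axis_convention see [disc_segmentation()].
#' @param seed RNG seed for simulated inputs.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(tsl_ms = c(2, 10, 20, 40, 60),
                       t_min = 1, t_max = 500, noise_sigma = 0,
                       np_fraction = 0.40, min_voxels = 10L,
                       axis_convention = list(row = "superior-inferior",
                                              col = "anterior-posterior",
                                              anterior = "low-col"),
                       seed = 20230101, out_dir = tempfile("nprelax_run_")) {
  check_tsl(tsl_ms)
  if (t_min <= 0 || t_max <= t_min) stop("need 0 < t_min < t_max")
  if (!(np_fraction > 0 && np_fraction <= 1))
    stop("np_fraction must be in (0, 1]")
  structure(as.list(environment()), class = "run_config")
}

write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(path))
}
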