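#' Disc segmentation volume
#'
#' Labelled voxel masks for the five lumbar discs over the (typically four)
#' mid-sagittal slices.  Label 0 is background; labels 1..5 are the L1-L2
#' through L5-S1 discs.
#'
#' @param labels integer array `(slice, row, column)` with values in 0..5.
#' @param spacing_mm voxel spacing `(slice, row, column)` in mm.
#' @param axis_convention named list mapping array axes to anatomy.  The
#'   default declares rows as the superior-inferior axis, columns as the
#'   anterior-posterior axis, with anterior at low column index.
#' @return An object of class `disc_segmentation`.
#' @export
disc_segmentation <- function(labels, spacing_mm = c(4, 1, 1),
                              axis_convention = list(row = "superior-inferior",
                                                     col = "anterior-posterior",
                                                     anterior = "low-col")) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array (slice, row, column)")
  lab <- unique(as.vector(labels))
  if (!all(lab %in% 0:5)) stop("labels must be integers in 0..5")
  if (is.null(axis_convention$row) || is.null(axis_convention$col))
    stop("axis_convention must name the row and col axes")
  structure(list(labels = labels, spacing_mm = as.numeric(spacing_mm),
                 axis_convention = axis_convention),
            class = "disc_segmentation")
}

#' Disc level labels
#'
#' @return character vector of the five lumbar disc levels in
#'   superior-to-inferior order.
#' @export
disc_levels <- function() c("L1L2", "L2L3", "L3L4", "L4L5", "L5S1")

level_code <- function(level) {
  i <- match(level, disc_levels())
  if (is.na(i)) stop("unknown disc level: ", level)
  i
}

#' Principal axes of a voxel point set
#'
#' Diagonalises the second-moment (rotational inertia) tensor of a set of
#' in-plane voxel coordinates about their centroid.  The returned rotation
#' maps original (anterior-posterior, superior-inferior) mm coordinates into
#' the principal frame with the major axis first.  Sign convention: the
#' major axis has positive dot product with the anatomical
#' anterior-to-posterior direction.
#'
#' @param coords_mm numeric matrix, one row per voxel, columns
#'   `(ap_mm, si_mm)`; >= 3 non-collinear points.
#' @param tie_ratio eigenvalue ratio below which the tensor is treated as
#'   isotropic: the identity rotation is returned with a `degenerate`
#'   attribute and a warning.
#' @return list with `rotation` (2 x 2, rows are the principal axes),
#'   `eigenvalues` (decreasing), `angle_deg` (major-axis angle from the AP
#'   axis), `degenerate` flag.
#' @export
principal_axes <- function(coords_mm, tie_ratio = 1.05) {
  coords_mm <- as.matrix(coords_mm)
  if (nrow(coords_mm) < 3L)
    stop("degenerate geometry: need >= 3 voxels")
  ctr <- colMeans(coords_mm)
  X <- sweep(coords_mm, 2L, ctr)
  M <- crossprod(X) / nrow(X)               # second-moment tensor (mm^2)
  ev <- eigen(M, symmetric = TRUE)
  if (ev$values[2] <= ev$values[1] * 1e-10)
    stop("degenerate geometry: voxel set is collinear")

  degenerate <- ev$values[1] / ev$values[2] < tie_ratio
  if (degenerate) {
    warning("near-isotropic inertia tensor (eigenvalue ratio < ", tie_ratio,
            "); keeping identity rotation")
    R <- diag(2)
  } else {
    v1 <- ev$vectors[, 1L]
    if (v1[1] < 0) v1 <- -v1                # major axis points posterior
    v2 <- c(-v1[2], v1[1])                  # proper rotation (det = +1)
    R <- rbind(v1, v2, deparse.level = 0)
  }
  list(rotation = R, eigenvalues = ev$values,
       angle_deg = atan2(R[1, 2], R[1, 1]) * 180 / pi,
       degenerate = degenerate)
}

#' Standardize a disc mask into its principal-axis frame
#'
#' Pools the voxels of one disc level across all mid-sagittal slices,
#' converts indices to mm via the voxel spacing, recenters at the pooled
#' centroid and rotates in-plane (SI x AP only) into the principal frame of
#' the rotational inertia tensor.  Intensities are never resampled: the
#' voxel identities are kept so biomarkers are computed on original values.
#'
#' @param seg a [disc_segmentation()].
#' @param level disc level, one of [disc_levels()] or its 1..5 code.
#' @return An object of class `standardized_disc`: `level`, `voxel_idx`
#'   (matrix of `(slice, row, col)` 1-based indices), `coords_std` (matrix of
#'   principal-frame mm coordinates, axis 1 = major/AP axis, centroid
#'   origin), `rotation`, `eigenvalues`, `angle_deg`, `ap_extent_mm`,
#'   `degenerate`.
#' @export
standardize_disc <- function(seg, level) {
  stopifnot(inherits(seg, "disc_segmentation"))
  code <- if (is.character(level)) level_code(level) else as.integer(level)
  lvl <- disc_levels()[code]
  idx <- which(seg$labels == code, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("level ", lvl, " not present in segmentation")
  colnames(idx) <- c("slice", "row", "col")

  # voxel centers, 0-based indices scaled to mm; in-plane coords are
  # (AP, SI) per the axis convention (rows = SI, cols = AP)
  ap <- (idx[, "col"] - 1) * seg$spacing_mm[3]
  si <- (idx[, "row"] - 1) * seg$spacing_mm[2]
  if (identical(seg$axis_convention$anterior, "high-col")) ap <- -ap
  coords <- cbind(ap = ap, si = si)

  pa <- principal_axes(coords)
  ctr <- colMeans(coords)
  coords_std <- sweep(coords, 2L, ctr) %*% t(pa$rotation)
  colnames(coords_std) <- c("ap_std", "si_std")
  structure(list(level = lvl, voxel_idx = idx, coords_std = coords_std,
                 rotation = pa$rotation, eigenvalues = pa$eigenvalues,
                 angle_deg = pa$angle_deg,
                 ap_extent_mm = range(coords_std[, 1L]),
                 degenerate = pa$degenerate),
            class = "standardized_disc")
}

#' Extract the nucleus pulposus region of a standardized disc
#'
#' The nucleus pulposus (NP) is operationalised as the voxels whose
#' principal-frame AP coordinate lies within the central `fraction` of the
#' disc's AP extent: `|x1 - midpoint| <= fraction * (ap_max - ap_min) / 2`,
#' boundary inclusive.  The default 0.40 selects the central
#' anterior-posterior 40% of the disc.
#'
#' @param std a [standardize_disc()] result.
#' @param fraction AP fraction in (0, 1].
#' @return An object of class `np_region`: `level`, `np_voxel_idx` (subset of
#'   the disc's `(slice, row, col)` indices), `in_np` (logical selector over
#'   the disc's voxels), `fraction`.
#' @export
extract_np <- function(std, fraction = 0.40) {
  stopifnot(inherits(std, "standardized_disc"))
  if (!(fraction > 0 && fraction <= 1)) stop("`fraction` must be in (0, 1]")
  ext <- std$ap_extent_mm
  mid <- mean(ext)
  half <- fraction * diff(ext) / 2
  in_np <- abs(std$coords_std[, 1L] - mid) <= half + 1e-9
  if (!any(in_np)) stop("degenerate geometry: empty NP region")
  structure(list(level = std$level,
                 np_voxel_idx = std$voxel_idx[in_np, , drop = FALSE],
                 in_np = in_np, fraction = fraction),
            class = "np_region")
}
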