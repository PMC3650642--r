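# ROI measurements: volume, centre of mass, slice span.

#' ROI volume in mm^3
#'
#' Foreground voxel count times the voxel volume given by the affine
#' (absolute determinant of its 3x3 block); exact and deterministic.
#'
#' @param mask a [hab_mask()].
#' @return Volume in mm^3 (0 with a warning for an empty mask).
#' @export
mask_volume <- function(mask) {
  n <- sum(mask$data)
  if (n == 0) {
    warning("empty mask: volume is 0")
    return(0)
  }
  n * abs(det(mask$affine[1:3, 1:3]))
}

foreground_indices <- function(mask) {
  w <- which(mask$data == 1, arr.ind = TRUE)
  w - 1L   # 0-based
}

#' ROI centre of mass in world coordinates
#'
#' Unweighted mean of the world coordinates of the foreground voxel centres
#' (the ROI is binary; intensity weighting is not used).
#'
#' @param mask a non-empty [hab_mask()].
#' @return Named length-3 vector `(x, y, z)` in mm.
#' @export
mask_center_of_mass <- function(mask) {
  idx <- foreground_indices(mask)
  if (nrow(idx) == 0) stop("centre of mass undefined for an empty mask")
  w <- apply_affine(mask$affine, idx)
  stats::setNames(colMeans(w), c("x", "y", "z"))
}

#' Number of occupied slices along an axis
#'
#' @param mask a [hab_mask()].
#' @param axis `"x"`, `"y"` (coronal, default) or `"z"`.
#' @return Count of distinct slices containing at least one foreground voxel
#'   (0 for an empty mask).
#' @export
slice_span <- function(mask, axis = c("y", "x", "z")) {
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  idx <- foreground_indices(mask)
  if (nrow(idx) == 0) return(0L)
  length(unique(idx[, a]))
}

#' Measurement report for one or more masks
#'
#' @param masks a [hab_mask()] or list of them.
#' @return A data.frame with one row per mask: `label`, `n_voxels`,
#'   `volume_mm3`, `com_x`, `com_y`, `com_z`, `slice_span_y`.
#' @export
measure_mask <- function(masks) {
  if (inherits(masks, "hab_mask")) masks <- list(masks)
  do.call(rbind, lapply(masks, function(m) {
    com <- if (sum(m$data) > 0) mask_center_of_mass(m) else c(x = NA_real_, y = NA_real_, z = NA_real_)
    vol <- if (sum(m$data) > 0) mask_volume(m) else 0
    data.frame(label = m$label %||% "other",
               n_voxels = sum(m$data),
               volume_mm3 = vol,
               com_x = com[["x"]], com_y = com[["y"]], com_z = com[["z"]],
               slice_span_y = slice_span(m, "y"),
               row.names = NULL)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
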