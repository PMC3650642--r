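#' @importFrom stats rnorm sd var qf quantile
#' @importFrom utils head tail
NULL

# Voxel convention used throughout: indices are 0-based and the affine maps
# voxel *centres* to world millimetres. All canonical volumes are RAS+
# (+x right, +y anterior, +z superior).

#' Construct a 3D volume
#'
#' A `hab_volume` bundles a 3D intensity grid with its 4x4 voxel-to-world
#' affine. The affine maps 0-based voxel-centre indices to world coordinates
#' in millimetres.
#'
#' @param data 3D numeric array of intensities.
#' @param affine 4x4 numeric matrix; the upper-left 3x3 block must be
#'   nonsingular and the last row `(0, 0, 0, 1)`.
#' @param check validate invariants (default `TRUE`).
#' @return An object of class `hab_volume` with elements `data`, `affine` and
#'   `voxel_dims` (mm per axis, derived from the affine column norms).
#' @export
hab_volume <- function(data, affine, check = TRUE) {
  data <- as.array(data)
  affine <- as_affine(affine)
  if (check) {
    if (length(dim(data)) != 3L)
      stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions")
    if (abs(det(affine[1:3, 1:3])) < 1e-12)
      stop("affine rotation/scaling block is singular")
  }
  vd <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(data = data, affine = affine, voxel_dims = vd),
            class = "hab_volume")
}

as_affine <- function(affine) {
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("affine last row must be (0, 0, 0, 1)")
  storage.mode(affine) <- "double"
  affine
}

#' Construct a binary 3D mask
#'
#' A `hab_mask` is a `hab_volume` whose data are strictly 0/1, carrying a
#' label naming the structure. Masks always share the affine of the volume
#' they were traced on and are never resampled on write.
#'
#' @param data 3D array of 0/1 (logical or numeric).
#' @param affine 4x4 voxel-to-world affine (see [hab_volume()]).
#' @param label structure label, e.g. `"left_habenula"`, `"right_habenula"`
#'   or `"other"`.
#' @return An object of classes `hab_mask` and `hab_volume`.
#' @export
hab_mask <- function(data, affine, label = "other") {
  data <- as.array(data)
  if (is.logical(data)) data <- array(as.double(data), dim = dim(data))
  if (!all(data %in% c(0, 1)))
    stop("mask data must be binary (0/1)")
  vol <- hab_volume(data, affine)
  vol$label <- label
  class(vol) <- c("hab_mask", "hab_volume")
  vol
}

#' @export
print.hab_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, %.3g x %.3g x %.3g mm\n",
              class(x)[1], paste(dim(x$data), collapse = " x "),
              x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3]))
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Map voxel indices to world coordinates
#'
#' Applies the volume's affine to 0-based voxel indices, using the
#' voxel-centre convention.
#'
#' @param vol a `hab_volume`.
#' @param index integer triple, or an n x 3 matrix of 0-based indices.
#' @return A numeric length-3 vector (or n x 3 matrix) of world mm.
#' @export
voxel_to_world <- function(vol, index) {
  idx <- rbind_points(index)
  dm <- dim(vol$data)
  if (any(idx < 0) || any(idx >= matrix(dm, nrow(idx), 3, byrow = TRUE)))
    stop("voxel index out of bounds for grid ", paste(dm, collapse = "x"))
  out <- apply_affine(vol$affine, idx)
  if (is.null(dim(index)) && length(index) == 3L) drop(out) else out
}

#' Map world coordinates to (continuous) voxel indices
#'
#' Inverse of [voxel_to_world()]; returns continuous 0-based voxel
#' coordinates, which round to the generating index for on-grid points.
#'
#' @param vol a `hab_volume`.
#' @param world length-3 vector or n x 3 matrix of world mm.
#' @return Continuous voxel coordinates (not rounded, not bounds-checked).
#' @export
world_to_voxel <- function(vol, world) {
  pts <- rbind_points(world)
  out <- apply_affine(solve(vol$affine), pts)
  if (is.null(dim(world)) && length(world) == 3L) drop(out) else out
}

rbind_points <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("point must have 3 coordinates")
    matrix(as.double(p), 1L, 3L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("points must be n x 3")
    storage.mode(p) <- "double"
    p
  }
}

apply_affine <- function(affine, pts) {
  # pts: n x 3 -> n x 3
  t(affine[1:3, 1:3] %*% t(pts) + affine[1:3, 4])
}

#' Read a NIfTI-1 volume in canonical RAS+ orientation
#'
#' Reads a 3D NIfTI-1 file and reorders its data axes (flipping/permuting as
#' needed) so that the stored grid follows RAS+; the affine is adjusted so
#' the world coordinate of every voxel centre is unchanged.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [hab_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D image, got ", length(dim(img)), "D: ", path)
  RNifti::orientation(img) <- "RAS"
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  hab_volume(array(as.double(img), dim = dim(img)), aff)
}

#' Read a NIfTI-1 binary mask
#'
#' @inheritParams read_volume
#' @param label structure label to attach (see [hab_mask()]).
#' @return A [hab_mask()].
#' @export
read_mask <- function(path, label = "other") {
  vol <- read_volume(path)
  hab_mask(vol$data != 0, vol$affine, label = label)
}

#' Write a volume or mask to NIfTI-1
#'
#' Volumes are stored as float32; masks as unsigned 8-bit. The affine is
#' written verbatim into the sform (code 2); data are never resampled.
#'
#' @param vol a `hab_volume` or `hab_mask`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  datatype <- if (inherits(vol, "hab_mask")) "uint8" else "float"
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- write_volume
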