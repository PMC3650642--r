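# AC-PC reorientation: a proper rigid motion taking native world coordinates
# to the commissural frame, with the AC at the origin, the PC on the -y axis
# and the midsagittal plane at x = 0.

#' Commissural landmark set
#'
#' Holds the three manually placed points that define the AC-PC frame: the
#' midpoint of the anterior commissure, the midpoint of the posterior
#' commissure, and any point on the interhemispheric (midsagittal) plane well
#' away from the AC-PC line.
#'
#' @param ac,pc,midsagittal world points (mm), length-3 numeric.
#' @return An object of class `hab_acpc_landmarks`.
#' @export
acpc_landmarks <- function(ac, pc, midsagittal) {
  ac <- as_point3(ac); pc <- as_point3(pc); ms <- as_point3(midsagittal)
  d <- sqrt(sum((ac - pc)^2))
  if (d < 1e-9) stop("degenerate geometry: AC and PC coincide")
  if (d < 15 || d > 40)
    warning(sprintf("AC-PC distance %.1f mm outside the plausible 15-40 mm range", d))
  # angular separation between the AC->PC line and the AC->midsagittal vector
  u <- (pc - ac) / d
  v <- ms - ac
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("degenerate geometry: midsagittal point coincides with AC")
  ang <- acos(pmin(1, abs(sum(u * v) / nv))) * 180 / pi
  if (ang <= 5)
    stop(sprintf("degenerate geometry: midsagittal point within %.2f degrees of the AC-PC line", ang))
  structure(list(ac = ac, pc = pc, midsagittal = ms), class = "hab_acpc_landmarks")
}

as_point3 <- function(p) {
  p <- as.double(unlist(p))
  if (length(p) != 3L || anyNA(p)) stop("expected a finite length-3 point")
  p
}

#' Proper rigid motion
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector, mm.
#' @return An object of class `hab_rigid_transform`. The transform acts as
#'   `p -> rotation %*% p + translation`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as_point3(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation determinant must be +1 (no reflection/scaling)")
  structure(list(rotation = rotation, translation = translation),
            class = "hab_rigid_transform")
}

#' @export
print.hab_rigid_transform <- function(x, ...) {
  cat("<hab_rigid_transform>\n")
  m <- cbind(x$rotation, x$translation)
  dimnames(m) <- list(c("x", "y", "z"), c("r1", "r2", "r3", "t"))
  print(round(m, 6))
  invisible(x)
}

#' Apply a rigid transform to world points
#'
#' @param transform a [rigid_transform()].
#' @param points length-3 vector or n x 3 matrix of world mm.
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(transform, points) {
  pts <- rbind_points(points)
  out <- t(transform$rotation %*% t(pts) + transform$translation)
  if (is.null(dim(points)) && length(points) == 3L) drop(out) else out
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse `hab_rigid_transform`.
#' @export
transform_invert <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation))
}

#' Compose two rigid transforms
#' @param first,second rigid transforms; the result applies `first` then
#'   `second`.
#' @return A `hab_rigid_transform` equal to `second o first`.
#' @export
transform_compose <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  drop(second$rotation %*% first$translation) + second$translation)
}

#' @rdname rigid_transform
#' @param transform a `hab_rigid_transform`.
#' @return `transform_matrix()`: the equivalent 4x4 homogeneous matrix.
#' @export
transform_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Compute the AC-PC reorientation transform
#'
#' Returns the proper rigid motion that places the AC at the world origin,
#' the PC on the -y axis at the same x and z as the AC, and the midsagittal
#' plane at x = 0 (so that the brain is symmetric about a sagittal plane
#' containing the AC-PC line). The roll about the AC-PC axis is fixed by the
#' user-supplied midsagittal point, which is mapped into the +z half of the
#' x = 0 plane.
#'
#' @param landmarks an [acpc_landmarks()] set.
#' @return A [rigid_transform()] `T` with `T(ac) = (0,0,0)`,
#'   `T(pc) = (0, -|ac - pc|, 0)` and `T(midsagittal)` having x = 0, all
#'   within 1e-6 mm.
#' @export
compute_acpc_transform <- function(landmarks) {
  if (!inherits(landmarks, "hab_acpc_landmarks"))
    landmarks <- acpc_landmarks(landmarks$ac, landmarks$pc, landmarks$midsagittal)
  ac <- landmarks$ac; pc <- landmarks$pc; ms <- landmarks$midsagittal
  yhat <- (ac - pc); yhat <- yhat / sqrt(sum(yhat^2))
  u <- ms - ac
  zdir <- u - sum(u * yhat) * yhat
  nz <- sqrt(sum(zdir^2))
  if (nz < 1e-9) stop("degenerate geometry: midsagittal point collinear with AC-PC")
  zhat <- zdir / nz
  xhat <- cross3(yhat, zhat)
  rot <- rbind(xhat, yhat, zhat)
  dimnames(rot) <- NULL
  rigid_transform(rot, -drop(rot %*% ac))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Reorient a volume by updating its header affine only
#'
#' Composes the rigid transform with the volume's affine. The data grid is
#' untouched (no resampling, no interpolation), so the operation is lossless:
#' only the mapping from voxel indices to world coordinates changes.
#'
#' @param vol a `hab_volume` or `hab_mask`.
#' @param transform a [rigid_transform()].
#' @return The input volume with `affine = T %*% affine`.
#' @export
apply_transform_header <- function(vol, transform) {
  aff <- transform_matrix(transform) %*% vol$affine
  if (inherits(vol, "hab_mask")) hab_mask(vol$data, aff, label = vol$label)
  else hab_volume(vol$data, aff)
}

#' Resample a volume onto an axis-aligned AC-PC grid
#'
#' Explicit opt-in alternative to header-only reorientation for users who
#' need grid axes aligned with the commissural frame (e.g. for slice-wise
#' tracing). The image is interpolated exactly once: trilinearly for
#' intensities, nearest-neighbour for masks (which therefore stay binary).
#'
#' @param vol a `hab_volume` or `hab_mask`.
#' @param transform the AC-PC [rigid_transform()].
#' @param voxel_size output isotropic voxel size in mm (> 0).
#' @param fov optional 2 x 3 matrix `rbind(min, max)` of the output field of
#'   view in AC-PC world mm; defaults to the transformed bounding box of the
#'   input grid. A requested FOV that fails to cover the input produces a
#'   warning and a cropped output.
#' @param interpolation `"trilinear"` or `"nearest"`; masks force nearest.
#' @return A resampled `hab_volume`/`hab_mask` with a diagonal affine.
#' @export
resample_to_acpc_grid <- function(vol, transform, voxel_size,
                                  fov = NULL,
                                  interpolation = c("trilinear", "nearest")) {
  if (voxel_size <= 0) stop("voxel_size must be positive")
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(vol, "hab_mask")
  if (is_mask) interpolation <- "nearest"

  dm <- dim(vol$data)
  corners <- as.matrix(expand.grid(c(0, dm[1] - 1), c(0, dm[2] - 1), c(0, dm[3] - 1)))
  wc <- transform_points(transform, apply_affine(vol$affine, corners))
  lo <- apply(wc, 2, min); hi <- apply(wc, 2, max)
  if (!is.null(fov)) {
    fov <- as.matrix(fov)
    if (any(fov[1, ] > lo + 1e-9) || any(fov[2, ] < hi - 1e-9))
      warning("requested field of view does not cover the input volume; output cropped")
    lo <- fov[1, ]; hi <- fov[2, ]
  }
  n_out <- pmax(1L, as.integer(floor((hi - lo) / voxel_size)) + 1L)
  out_aff <- diag(c(rep(voxel_size, 3), 1))
  out_aff[1:3, 4] <- lo

  # output voxel centres -> AC-PC world -> native world -> input voxel coords
  grid <- as.matrix(expand.grid(0:(n_out[1] - 1L), 0:(n_out[2] - 1L), 0:(n_out[3] - 1L)))
  w_acpc <- apply_affine(out_aff, grid)
  w_native <- transform_points(transform_invert(transform), w_acpc)
  v_in <- apply_affine(solve(vol$affine), w_native)

  vals <- if (interpolation == "trilinear") interp_trilinear(vol$data, v_in)
          else interp_nearest(vol$data, v_in)
  out <- array(vals, dim = n_out)
  if (is_mask) hab_mask(out != 0, out_aff, label = vol$label)
  else hab_volume(out, out_aff)
}

interp_nearest <- function(arr, v) {
  dm <- dim(arr)
  idx <- round(v)
  ok <- idx[, 1] >= 0 & idx[, 1] < dm[1] &
        idx[, 2] >= 0 & idx[, 2] < dm[2] &
        idx[, 3] >= 0 & idx[, 3] < dm[3]
  out <- numeric(nrow(v))
  if (any(ok))
    out[ok] <- arr[cbind(idx[ok, 1] + 1L, idx[ok, 2] + 1L, idx[ok, 3] + 1L)]
  out
}

interp_trilinear <- function(arr, v) {
  dm <- dim(arr)
  f <- floor(v)
  d <- v - f
  out <- numeric(nrow(v))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- f[, 1] + cx; iy <- f[, 2] + cy; iz <- f[, 3] + cz
    w <- (if (cx) d[, 1] else 1 - d[, 1]) *
         (if (cy) d[, 2] else 1 - d[, 2]) *
         (if (cz) d[, 3] else 1 - d[, 3])
    ok <- ix >= 0 & ix < dm[1] & iy >= 0 & iy < dm[2] & iz >= 0 & iz < dm[3] & w > 0
    if (any(ok))
      out[ok] <- out[ok] + w[ok] * arr[cbind(ix[ok] + 1L, iy[ok] + 1L, iz[ok] + 1L)]
  }
  out
}

#' Residual midsagittal asymmetry after reorientation
#'
#' Quality-control number: the absolute x coordinate (mm) of the midsagittal
#' landmark after applying the transform. The protocol does not fix a
#' symmetry tolerance, so the residual is reported rather than thresholded.
#'
#' @param landmarks an [acpc_landmarks()] set.
#' @param transform the computed [rigid_transform()].
#' @return Absolute residual |x| in mm (0 for an exact transform).
#' @export
midsagittal_residual <- function(landmarks, transform) {
  abs(transform_points(transform, landmarks$midsagittal)[1])
}

#' Read landmarks from a JSON file
#'
#' AC-PC files hold named world points, e.g.
#' `{"ac": [x,y,z], "pc": [...], "midsagittal": [...]}`. Per-slice habenula
#' landmark files hold an array of records with fields
#' `side, y_mm, Ax, Az, Bx, Bz, Cx, Cz`.
#'
#' @param path JSON file path.
#' @return An [acpc_landmarks()] object, or a list of [slice_landmarks()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.list(obj) && all(c("ac", "pc", "midsagittal") %in% names(obj)))
    return(acpc_landmarks(obj$ac, obj$pc, obj$midsagittal))
  if (is.data.frame(obj)) {
    return(lapply(seq_len(nrow(obj)), function(i)
      slice_landmarks(y_mm = obj$y_mm[i],
                      A = c(obj$Ax[i], obj$Az[i]),
                      B = c(obj$Bx[i], obj$Bz[i]),
                      C = c(obj$Cx[i], obj$Cz[i]),
                      side = obj$side[i])))
  }
  stop("unrecognised landmark file layout: ", path)
}

#' Write landmarks to a JSON file
#'
#' @param landmarks an [acpc_landmarks()] object or list of
#'   [slice_landmarks()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  if (inherits(landmarks, "hab_acpc_landmarks")) {
    obj <- list(ac = landmarks$ac, pc = landmarks$pc,
                midsagittal = landmarks$midsagittal)
  } else {
    obj <- do.call(rbind, lapply(landmarks, function(lm)
      data.frame(side = lm$side, y_mm = lm$y_mm,
                 Ax = lm$A[1], Az = lm$A[2],
                 Bx = lm$B[1], Bz = lm$B[2],
                 Cx = lm$C[1], Cz = lm$C[2])))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
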