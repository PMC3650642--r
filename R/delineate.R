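# Geometric delineation of the habenula in posterior coronal slices.
#
# In slices where the posterior/habenular commissure is present the lateral
# boundary cannot be followed by image contrast, so it is constructed from
# three manually placed in-plane points:
#   A - intersection of the medial habenula boundary with the PC/HC,
#   B - dorsal point of the medial boundary where it meets the MD thalamus,
#   C - lateral aspect of the mesopontine junction near the tentorial
#       incisure (used only to direct the lateral edge).
# The lateral edge runs through B and C; the ventral edge runs horizontally
# and laterally from A; their intersection is the ventrolateral apex. The
# medial edge (third-ventricle CSF) connects A to B. The resulting triangle
# [A, B, apex] is filled on the voxel grid.

#' Per-slice habenula landmarks
#'
#' In-plane points are `(x, z)` pairs in world mm on a coronal plane at
#' `y_mm`. See the package vignette for the anatomical definitions of A, B
#' and C.
#'
#' @param y_mm coronal plane coordinate (world mm, AC-PC frame).
#' @param A,B,C in-plane `(x, z)` points, mm.
#' @param side `"left"` or `"right"`.
#' @return An object of class `hab_slice_landmarks`.
#' @export
slice_landmarks <- function(y_mm, A, B, C, side = c("right", "left")) {
  side <- match.arg(side)
  A <- as_point2(A); B <- as_point2(B); C <- as_point2(C)
  pts <- rbind(A, B, C)
  dd <- as.matrix(dist(pts))
  if (min(dd[upper.tri(dd)]) <= 0.1)
    stop("degenerate landmarks: A, B, C must be pairwise > 0.1 mm apart")
  if (B[2] <= A[2]) stop("landmark B must be dorsal to A (B.z > A.z)")
  # C at B's height is admitted here so that the horizontal-edge case
  # surfaces as a no-intersection error in apex_from_landmarks()
  if (C[2] > B[2]) stop("landmark C must be ventral to B (C.z < B.z)")
  xs <- pts[, 1]
  if (side == "right" && any(xs < -1))
    warning("right-side landmarks have x < -1 mm; check hemisphere")
  if (side == "left" && any(xs > 1))
    warning("left-side landmarks have x > +1 mm; check hemisphere")
  structure(list(y_mm = as.double(y_mm), A = A, B = B, C = C, side = side),
            class = "hab_slice_landmarks")
}

as_point2 <- function(p) {
  p <- as.double(unlist(p))
  if (length(p) != 2L || anyNA(p)) stop("expected a finite in-plane (x, z) point")
  p
}

lateral_sign <- function(side) if (side == "right") 1 else -1

#' Ventrolateral apex of the posterior habenula boundary
#'
#' Intersects the lateral edge (the line through B and C) with the ventral
#' edge (the horizontal line through A).
#'
#' @param lm a [slice_landmarks()] object.
#' @return In-plane `(x, z)` point with `z = A.z`, collinear with B and C,
#'   lateral to A.
#' @export
apex_from_landmarks <- function(lm) {
  A <- lm$A; B <- lm$B; C <- lm$C
  dz <- C[2] - B[2]
  if (abs(dz) <= 1e-6)
    stop("no intersection: the B-C lateral edge is horizontal")
  t <- (A[2] - B[2]) / dz
  apex <- c(B[1] + t * (C[1] - B[1]), A[2])
  s <- lateral_sign(lm$side)
  if (s * (apex[1] - A[1]) <= 1e-9)
    stop("degenerate polygon: apex is not lateral to A")
  apex
}

#' Triangular boundary polygon for a posterior slice
#'
#' @param lm a [slice_landmarks()] object.
#' @return An object of class `hab_slice_polygon` with ordered vertices
#'   `[A, B, apex]`, the slice coordinate, side and signed-area-derived
#'   `area_mm2`.
#' @export
posterior_slice_polygon <- function(lm) {
  apex <- apex_from_landmarks(lm)
  verts <- rbind(A = lm$A, B = lm$B, apex = apex)
  area <- polygon_area(verts)
  if (area <= 0) stop("degenerate polygon: zero area")
  structure(list(vertices = verts, y_mm = lm$y_mm, side = lm$side,
                 area_mm2 = area),
            class = "hab_slice_polygon")
}

#' Shoelace area of a simple polygon
#' @param vertices n x 2 matrix of ordered in-plane vertices.
#' @return Unsigned area (mm^2).
#' @export
polygon_area <- function(vertices) {
  x <- vertices[, 1]; z <- vertices[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * z[j] - x[j] * z)) / 2
}

# Inclusive point-in-triangle test via half-plane signs, vectorised over
# points. Points on an edge (within eps) count as inside: ambiguous voxels
# on the medial boundary are included in the ROI.
points_in_triangle <- function(px, pz, tri, eps = 1e-9) {
  e <- function(p1, p2) (p2[1] - p1[1]) * (pz - p1[2]) - (p2[2] - p1[2]) * (px - p1[1])
  s1 <- e(tri[1, ], tri[2, ])
  s2 <- e(tri[2, ], tri[3, ])
  s3 <- e(tri[3, ], tri[1, ])
  # orientation of the triangle itself
  o <- (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
       (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1])
  s <- sign(o)
  s * s1 >= -eps & s * s2 >= -eps & s * s3 >= -eps
}

require_axis_aligned <- function(vol) {
  rot <- vol$affine[1:3, 1:3]
  off <- rot; diag(off) <- 0
  if (max(abs(off)) > 1e-6 || any(diag(rot) <= 0))
    stop("volume grid is not axis-aligned with the world frame; ",
         "resample with resample_to_acpc_grid() before slice-wise tracing")
  invisible(vol)
}

# Map a world y coordinate to a 0-based coronal slice index. Nearest slice;
# an exact midpoint rounds toward posterior (smaller y).
y_to_slice <- function(vol, y_mm) {
  idx <- (y_mm - vol$affine[2, 4]) / vol$affine[2, 2]
  j <- as.integer(ceiling(idx - 0.5))
  if (j < 0L || j >= dim(vol$data)[2])
    stop(sprintf("coronal coordinate y = %.2f mm outside the volume", y_mm))
  j
}

#' Fill a slice polygon on the voxel grid
#'
#' Marks as foreground every voxel of the nearest coronal slice whose
#' in-plane centre lies inside or on the boundary of the polygon (inclusive
#' boundary handling: ambiguous medial-boundary voxels are included).
#'
#' @param poly a [posterior_slice_polygon()].
#' @param vol the `hab_volume` defining the grid (must be axis-aligned; see
#'   [resample_to_acpc_grid()]).
#' @param y_mm coronal coordinate; defaults to the polygon's own `y_mm`.
#' @return A single-slice [hab_mask()] labelled by side.
#' @export
rasterize_polygon <- function(poly, vol, y_mm = poly$y_mm) {
  require_axis_aligned(vol)
  j <- y_to_slice(vol, y_mm)
  dm <- dim(vol$data)
  xs <- vol$affine[1, 4] + vol$affine[1, 1] * (0:(dm[1] - 1))
  zs <- vol$affine[3, 4] + vol$affine[3, 3] * (0:(dm[3] - 1))
  out <- array(0, dim = dm)
  if (poly$area_mm2 > 0) {
    g <- expand.grid(x = xs, z = zs)
    inside <- points_in_triangle(g$x, g$z, poly$vertices)
    if (!any(inside))
      warning("polygon lies entirely outside the field of view; empty mask")
    out[, j + 1L, ] <- array(as.double(inside), dim = c(dm[1], dm[3]))
  }
  hab_mask(out, vol$affine, label = paste0(poly$side, "_habenula"))
}

#' Intensity references for anterior-slice delineation
#'
#' @param csf_mean mean intensity of a third-ventricle CSF sample.
#' @param md_mean mean intensity of an MD-thalamus sample.
#' @param seed in-plane world `(x, z)` mm of a point inside the habenula.
#' @return An object of class `hab_intensity_refs`. On T1-weighted images
#'   CSF must be darker than MD grey matter (`csf_mean < md_mean`).
#' @export
intensity_references <- function(csf_mean, md_mean, seed) {
  if (!(csf_mean < md_mean))
    stop("invalid references: on T1-weighted images csf_mean must be < md_mean")
  structure(list(csf_mean = as.double(csf_mean), md_mean = as.double(md_mean),
                 seed = as_point2(seed)),
            class = "hab_intensity_refs")
}

#' Region-grow the habenula in an anterior slice
#'
#' In the most anterior slice(s) the PC/HC is absent and the stria
#' medullaris / fasciculus retroflexus provide enough contrast to follow the
#' habenula boundary directly. A 2D region is grown from the seed over
#' 4-connected voxels whose intensity is at least
#' `(md_mean + seed-region mean) / 2`, where the seed-region mean is taken
#' over the 3x3 in-plane neighbourhood of the seed. Growth is clipped to a
#' box of half-width `max_extent` around the seed; a region that reaches the
#' clip box on two or more sides indicates insufficient contrast and raises
#' an error.
#'
#' @param vol axis-aligned `hab_volume`.
#' @param y_mm coronal coordinate of the anterior slice.
#' @param refs an [intensity_references()] object.
#' @param max_extent clip-box half-width, mm (default 4).
#' @param side `"left"` or `"right"` (label only).
#' @return A single-slice [hab_mask()] containing the seed.
#' @export
anterior_slice_roi <- function(vol, y_mm, refs, max_extent = 4,
                               side = c("right", "left")) {
  side <- match.arg(side)
  require_axis_aligned(vol)
  j <- y_to_slice(vol, y_mm)
  dm <- dim(vol$data)
  sl <- vol$data[, j + 1L, ]                       # nx x nz in-plane
  # seed voxel (0-based in-plane indices)
  si <- round((refs$seed[1] - vol$affine[1, 4]) / vol$affine[1, 1])
  sk <- round((refs$seed[2] - vol$affine[3, 4]) / vol$affine[3, 3])
  if (si < 0 || si >= dm[1] || sk < 0 || sk >= dm[3])
    stop("seed point outside the field of view")
  seed_lin <- si + 1L + sk * dm[1]

  out <- array(0, dim = dm)
  if (sl[seed_lin] < refs$md_mean) {
    warning("seed intensity below md_mean: inverted contrast, returning seed-only mask")
    out[si + 1L, j + 1L, sk + 1L] <- 1
    return(hab_mask(out, vol$affine, label = paste0(side, "_habenula")))
  }
  nb <- expand.grid(i = pmax(0, si - 1):pmin(dm[1] - 1, si + 1),
                    k = pmax(0, sk - 1):pmin(dm[3] - 1, sk + 1))
  seed_region_mean <- mean(sl[cbind(nb$i + 1L, nb$k + 1L)])
  tau <- (refs$md_mean + seed_region_mean) / 2

  # clip box in voxel indices
  ri <- round(max_extent / vol$affine[1, 1]); rk <- round(max_extent / vol$affine[3, 3])
  i_lo <- max(0L, si - ri); i_hi <- min(dm[1] - 1L, si + ri)
  k_lo <- max(0L, sk - rk); k_hi <- min(dm[3] - 1L, sk + rk)

  nx <- dm[1]
  visited <- logical(nx * dm[3])
  grown <- logical(nx * dm[3])
  frontier <- seed_lin
  visited[seed_lin] <- TRUE
  grown[seed_lin] <- sl[seed_lin] >= tau
  frontier <- frontier[grown[frontier]]
  while (length(frontier)) {
    i0 <- (frontier - 1L) %% nx          # 0-based x
    k0 <- (frontier - 1L) %/% nx         # 0-based z
    cand_i <- c(i0 - 1L, i0 + 1L, i0, i0)
    cand_k <- c(k0, k0, k0 - 1L, k0 + 1L)
    ok <- cand_i >= i_lo & cand_i <= i_hi & cand_k >= k_lo & cand_k <= k_hi
    lin <- cand_i[ok] + 1L + cand_k[ok] * nx
    lin <- unique(lin[!visited[lin]])
    visited[lin] <- TRUE
    accept <- lin[sl[lin] >= tau]
    grown[accept] <- TRUE
    frontier <- accept
  }
  gi <- ((which(grown) - 1L) %% nx)
  gk <- ((which(grown) - 1L) %/% nx)
  touches <- sum(any(gi == i_lo), any(gi == i_hi), any(gk == k_lo), any(gk == k_hi))
  if (touches >= 2)
    stop("leakage: grown region reaches the clip box on ", touches,
         " sides; image contrast insufficient for region growing")
  out_sl <- array(0, dim = c(dm[1], dm[3]))
  out_sl[grown] <- 1
  out[, j + 1L, ] <- out_sl
  hab_mask(out, vol$affine, label = paste0(side, "_habenula"))
}

#' Include ambiguous dark-grey voxels on the medial boundary
#'
#' Optional refinement: dilate the mask by one voxel in the medial direction
#' (toward the midline), restricted to voxels whose intensity lies strictly
#' between the CSF reference and the current ROI mean — the "ambiguous"
#' partial-volume voxels at the CSF border, which likely contain habenular
#' tissue.
#'
#' @param mask a [hab_mask()] on an axis-aligned grid.
#' @param vol the intensity `hab_volume` on the same grid.
#' @param csf_mean CSF reference intensity.
#' @param side `"left"` or `"right"`; medial is -x for right, +x for left.
#' @return The augmented `hab_mask`.
#' @export
include_ambiguous_medial <- function(mask, vol, csf_mean, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(all(dim(mask$data) == dim(vol$data)))
  roi_mean <- mean(vol$data[mask$data == 1])
  shift <- if (side == "right") 1L else -1L   # medial neighbour is at x - shift
  dm <- dim(mask$data)
  m <- mask$data
  cand <- array(0, dim = dm)
  if (shift == 1L) cand[1:(dm[1] - 1), , ] <- m[2:dm[1], , ]
  else cand[2:dm[1], , ] <- m[1:(dm[1] - 1), , ]
  add <- cand == 1 & m == 0 & vol$data > csf_mean & vol$data < roi_mean
  m[add] <- 1
  hab_mask(m, mask$affine, label = mask$label)
}

#' Assemble per-slice masks into a habenula ROI
#'
#' Unions contiguous single-slice masks and validates the anterior-posterior
#' span: at 0.77 mm slice spacing the habenula spans three to five coronal
#' slices; the admissible range is rescaled proportionally for other
#' spacings, and a span outside it produces a warning.
#'
#' @param slices list of single-slice [hab_mask()]s on a common grid.
#' @param posterior_y,anterior_y optional explicit slice bounds (world mm);
#'   slices outside `[posterior_y, anterior_y]` raise an error.
#' @return The union `hab_mask`, with attribute `slice_span` (integer).
#' @export
assemble_roi <- function(slices, posterior_y = NULL, anterior_y = NULL) {
  stopifnot(length(slices) >= 1)
  aff <- slices[[1]]$affine
  for (s in slices)
    if (max(abs(s$affine - aff)) > 1e-9)
      stop("slice masks are not on a common grid")
  js <- vapply(slices, function(s) {
    j <- unique(which(apply(s$data, 2, sum) > 0)) - 1L
    if (length(j) != 1L) stop("each input mask must occupy exactly one coronal slice")
    j
  }, integer(1))
  sp <- aff[2, 2]
  ys <- aff[2, 4] + sp * js
  if (!is.null(posterior_y) && !is.null(anterior_y) && posterior_y > anterior_y)
    stop("posterior_y must not exceed anterior_y")
  if (!is.null(posterior_y) && any(ys < posterior_y - sp / 2))
    stop("slice mask posterior to the stated posterior boundary")
  if (!is.null(anterior_y) && any(ys > anterior_y + sp / 2))
    stop("slice mask anterior to the stated anterior boundary")
  js_sorted <- sort(unique(js))
  if (!all(diff(js_sorted) == 1L))
    stop("gap in slice coverage: slices are not contiguous in y")
  n_slices <- length(js_sorted)
  lo <- max(1, round(3 * 0.77 / sp)); hi <- round(5 * 0.77 / sp)
  if (n_slices < lo || n_slices > hi)
    warning(sprintf("ROI spans %d coronal slices; expected %d-%d at %.2f mm spacing",
                    n_slices, lo, hi, sp))
  data <- Reduce(function(a, b) pmax(a, b), lapply(slices, `[[`, "data"))
  out <- hab_mask(data, aff, label = slices[[1]]$label)
  attr(out, "slice_span") <- n_slices
  out
}

#' Delineate a habenula ROI from per-slice landmarks
#'
#' Convenience wrapper: builds the geometric polygon mask for every
#' posterior-slice landmark set, optionally adds anterior slices by
#' intensity-assisted region growing, and assembles the result.
#'
#' @param vol axis-aligned `hab_volume` (AC-PC frame).
#' @param landmarks list of [slice_landmarks()] for the posterior slices
#'   (one side only).
#' @param anterior optional list of `list(y_mm =, refs =)` entries for
#'   anterior slices, passed to [anterior_slice_roi()].
#' @param posterior_y,anterior_y explicit ROI bounds, passed to
#'   [assemble_roi()].
#' @return A [hab_mask()] for the requested side.
#' @export
delineate_habenula <- function(vol, landmarks, anterior = NULL,
                               posterior_y = NULL, anterior_y = NULL) {
  side <- landmarks[[1]]$side
  slices <- lapply(landmarks, function(lm)
    rasterize_polygon(posterior_slice_polygon(lm), vol))
  if (!is.null(anterior))
    slices <- c(slices, lapply(anterior, function(a)
      anterior_slice_roi(vol, a$y_mm, a$refs, side = side)))
  assemble_roi(slices, posterior_y = posterior_y, anterior_y = anterior_y)
}
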