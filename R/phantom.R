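# Synthetic epithalamic phantom: a T1-like neighbourhood of the habenula
# with ground-truth masks and landmarks, so the reorientation, delineation,
# volumetry, reliability and contamination modules can all be exercised
# without real scans. The geometry emulates the coronal appearance of the
# region: a bright habenula pair protruding into the dark CSF of the third
# ventricle, darker MD thalamus laterally, the PC/HC white-matter band
# ventrally, the pineal stalk posteriorly and the stria medullaris
# anteriorly. Cross-sections are pyramidal (triangular) in posterior slices
# and oblong (rounded-rectangular) in anterior slices.

PHANTOM_LABELS <- data.frame(
  code = 0:7,
  name = c("background", "csf", "md_thalamus", "habenula_left",
           "habenula_right", "pc_hc", "pineal", "stria_medullaris"))

# Fixed anatomy of the default phantom (world mm, AC-PC frame, AC at origin).
phantom_geometry <- function(ap_extent) {
  list(
    ac = c(0, 0, 0), pc = c(0, -25, 0), midsagittal = c(0, -12.5, 20),
    x_med = 1.0,           # third-ventricle half-width: habenula medial wall
    z_A = 1.0,             # ventral boundary height of the posterior habenula
    y_post = -25.8,        # most posterior habenula slice boundary
    y_ant = -25.8 + ap_extent,
    pc_band = list(x = 3.2, z = c(-1.2, 0.8), y = c(-26.8, -24.3)),
    pineal = list(x = 2.2, z = c(0.5, 4.5), y = c(-30.2, -26.4)),
    stria = list(x = c(1.0, 2.4), z = c(3.5, 5.5), y_to = -16),
    block = list(x = 14, y = c(-34, -14), z = c(-7, 11)),
    # unit-scale cross-section parameters (scaled in-plane about point A)
    tri_B = c(0.5, 3.2), tri_apex = c(4.6, 0),
    obl_w = 4.2, obl_h = 2.4, obl_z_lo = 1.7, obl_r = 0.6)
}

# In-plane membership tests (right side; the left side mirrors x -> -x).
tri_vertices <- function(geo, s) {
  A <- c(geo$x_med, geo$z_A)
  rbind(A = A, B = A + s * geo$tri_B, apex = A + s * geo$tri_apex)
}

in_triangle_bary <- function(px, pz, tri) {
  # barycentric-coordinate membership, inclusive boundary
  v0 <- tri[2, ] - tri[1, ]; v1 <- tri[3, ] - tri[1, ]
  den <- v0[1] * v1[2] - v1[1] * v0[2]
  wx <- px - tri[1, 1]; wz <- pz - tri[1, 2]
  l1 <- (wx * v1[2] - v1[1] * wz) / den
  l2 <- (v0[1] * wz - wx * v0[2]) / den
  l1 >= -1e-9 & l2 >= -1e-9 & (l1 + l2) <= 1 + 1e-9
}

in_oblong <- function(px, pz, geo, s) {
  x0 <- geo$x_med; x1 <- x0 + s * geo$obl_w
  z0 <- geo$obl_z_lo; z1 <- z0 + s * geo$obl_h
  r <- s * geo$obl_r
  inside <- px >= x0 & px <= x1 & pz >= z0 & pz <= z1
  # round the four corners
  cx <- pmin(pmax(px, x0 + r), x1 - r)
  cz <- pmin(pmax(pz, z0 + r), z1 - r)
  inside & ((px - cx)^2 + (pz - cz)^2 <= r^2 + 1e-9 |
              (px >= x0 + r & px <= x1 - r) | (pz >= z0 + r & pz <= z1 - r))
}

hab_slice_membership <- function(px, pz, geo, s, posterior, side) {
  if (side == "left") px <- -px
  if (posterior) in_triangle_bary(px, pz, tri_vertices(geo, s)) else in_oblong(px, pz, geo, s)
}

# Voxelised habenula volume (one side) at in-plane scale s.
hab_voxel_count <- function(xs, zs, slice_ys, geo, s, posterior_flags) {
  g <- expand.grid(x = xs, z = zs)
  n <- 0L
  for (i in seq_along(slice_ys))
    n <- n + sum(hab_slice_membership(g$x, g$z, geo, s, posterior_flags[i], "right"))
  n
}

#' Generate a synthetic epithalamic phantom
#'
#' Builds a T1-like intensity volume, a structure label map, ground-truth
#' habenula masks per side, the commissural landmarks (AC, PC, midsagittal)
#' and the per-slice delineation landmarks (A, B, C) for every posterior
#' slice, plus intensity references and seeds for the anterior slices. The
#' in-plane cross-section scale is calibrated so that the voxelised
#' ground-truth volume matches `habenula_volume_target` as closely as the
#' grid allows (within about one voxel volume).
#'
#' @param grid_shape voxels per axis (default 64^3).
#' @param voxel_size isotropic voxel size, mm (default 0.77, the protocol's
#'   target resolution).
#' @param habenula_volume_target mm^3 per side (default 30; plausible adult
#'   range roughly 21-38).
#' @param ap_extent anterior-posterior habenula extent, mm (default 2.5).
#' @param intensities named vector `c(csf, md, habenula, wm)` on an
#'   arbitrary scale; the ordering `csf < md < habenula` is enforced
#'   (defaults 0.3, 1.0, 1.3, 1.6).
#' @param noise_sigma additive Gaussian noise SD, intensity units
#'   (default 0.02).
#' @param seed integer seed; the output is fully deterministic given the
#'   seed.
#' @return An object of class `hab_phantom`: `image` (`hab_volume`),
#'   `labels` (`hab_volume` of integer codes with a `label_table`
#'   attribute), `acpc` ([acpc_landmarks()]), `slice_landmarks`
#'   (`$left`/`$right` lists of [slice_landmarks()] for posterior slices),
#'   `anterior` (`$left`/`$right` lists of `list(y_mm, refs)` for anterior
#'   slices), `true_masks` (`$left`/`$right` [hab_mask()]), `true_volumes`
#'   (named mm^3), and the generating parameters.
#' @export
generate_phantom <- function(grid_shape = c(64, 64, 64), voxel_size = 0.77,
                             habenula_volume_target = 30, ap_extent = 2.5,
                             intensities = c(csf = 0.3, md = 1.0,
                                             habenula = 1.3, wm = 1.6),
                             noise_sigma = 0.02, seed) {
  if (missing(seed)) stop("seed is required")
  if (habenula_volume_target <= 0) stop("habenula_volume_target must be positive")
  if (ap_extent <= 0.5 || ap_extent >= 6) stop("ap_extent must lie in (0.5, 6) mm")
  if (!(intensities[["csf"]] < intensities[["md"]] &&
        intensities[["md"]] < intensities[["habenula"]]))
    stop("intensity ordering csf < md < habenula is required")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  grid_shape <- as.integer(grid_shape)

  geo <- phantom_geometry(ap_extent)
  vs <- voxel_size
  # x grid symmetric about the midsagittal plane so the two sides voxelise
  # identically; y places the AC near the anterior end of the grid
  origin <- c(-((grid_shape[1] - 1) / 2) * vs, -(grid_shape[2] - 9) * vs,
              -(grid_shape[3] / 2) * vs)
  affine <- diag(c(vs, vs, vs, 1)); affine[1:3, 4] <- origin
  xs <- origin[1] + vs * (0:(grid_shape[1] - 1))
  ys <- origin[2] + vs * (0:(grid_shape[2] - 1))
  zs <- origin[3] + vs * (0:(grid_shape[3] - 1))
  if (min(xs) > -14.5 || max(xs) < 14.5 || min(ys) > -34.5 || max(ys) < 0.5 ||
      min(zs) > -7.5 || max(zs) < 11.5)
    stop("grid too small to contain the phantom structures; ",
         "enlarge grid_shape or reduce voxel_size")

  # habenula slices: voxel-centre planes within the A-P extent
  slice_j <- which(ys >= geo$y_post & ys < geo$y_ant) - 1L
  if (length(slice_j) == 0) stop("grid too coarse: no coronal slice intersects the habenula")
  slice_ys <- ys[slice_j + 1L]
  posterior_flags <- slice_ys <= geo$pc_band$y[2]
  if (!any(posterior_flags))
    stop("no posterior (PC/HC-containing) habenula slice on this grid")

  # calibrate the in-plane scale so the voxelised volume hits the target
  vv <- vs^3
  fcount <- function(s) hab_voxel_count(xs, zs, slice_ys, geo, s, posterior_flags) * vv
  lo <- 0.4; hi <- 2.5
  if (fcount(hi) < habenula_volume_target)
    stop("habenula_volume_target unreachable within the phantom geometry")
  for (it in 1:45) {
    mid <- (lo + hi) / 2
    if (fcount(mid) < habenula_volume_target) lo <- mid else hi <- mid
  }
  s <- if (abs(fcount(lo) - habenula_volume_target) <
           abs(fcount(hi) - habenula_volume_target)) lo else hi

  # label painting (later paints overwrite earlier ones)
  lab <- array(0L, dim = grid_shape)
  X <- array(xs, dim = grid_shape)
  Y <- array(rep(ys, each = grid_shape[1]), dim = grid_shape)
  Z <- array(rep(zs, each = grid_shape[1] * grid_shape[2]), dim = grid_shape)
  blk <- abs(X) <= geo$block$x & Y >= geo$block$y[1] & Y <= geo$block$y[2] &
    Z >= geo$block$z[1] & Z <= geo$block$z[2]
  lab[blk] <- 2L                                            # MD thalamus
  lab[blk & abs(X) < geo$x_med] <- 1L                       # third ventricle CSF
  pcb <- geo$pc_band
  lab[abs(X) <= pcb$x & Z >= pcb$z[1] & Z <= pcb$z[2] &
        Y >= pcb$y[1] & Y <= pcb$y[2]] <- 5L                # PC/HC band
  pin <- geo$pineal
  lab[abs(X) <= pin$x & Z >= pin$z[1] & Z <= pin$z[2] &
        Y >= pin$y[1] & Y <= pin$y[2]] <- 6L                # pineal stalk
  st <- geo$stria
  lab[abs(X) >= st$x[1] & abs(X) <= st$x[2] & Z >= st$z[1] & Z <= st$z[2] &
        Y >= geo$y_ant & Y <= st$y_to] <- 7L                # stria medullaris

  g <- expand.grid(x = xs, z = zs)
  mask_r <- array(0, dim = grid_shape); mask_l <- array(0, dim = grid_shape)
  for (i in seq_along(slice_j)) {
    j1 <- slice_j[i] + 1L
    mr <- hab_slice_membership(g$x, g$z, geo, s, posterior_flags[i], "right")
    ml <- hab_slice_membership(g$x, g$z, geo, s, posterior_flags[i], "left")
    mask_r[, j1, ] <- array(as.double(mr), dim = grid_shape[c(1, 3)])
    mask_l[, j1, ] <- array(as.double(ml), dim = grid_shape[c(1, 3)])
  }
  lab[mask_l == 1] <- 3L
  lab[mask_r == 1] <- 4L

  img <- array(0, dim = grid_shape)
  img[lab == 1L] <- intensities[["csf"]]
  img[lab == 2L] <- intensities[["md"]]
  img[lab == 3L | lab == 4L] <- intensities[["habenula"]]
  img[lab == 5L | lab == 7L] <- intensities[["wm"]]
  img[lab == 6L] <- 1.25
  img[abs(X) <= 1.5 & abs(Y) <= 1.2 & abs(Z) <= 1.2] <- intensities[["wm"]]  # AC marker
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    img <- img + array(rnorm(length(img), 0, noise_sigma), dim = grid_shape)
  }

  # ground-truth landmarks
  tri <- tri_vertices(geo, s)
  C_pt <- tri["B", ] + 1.8 * (tri["apex", ] - tri["B", ])
  mk_lm <- function(y, side) {
    flip <- if (side == "right") 1 else -1
    slice_landmarks(y_mm = y,
                    A = c(flip * tri["A", 1], tri["A", 2]),
                    B = c(flip * tri["B", 1], tri["B", 2]),
                    C = c(flip * C_pt[1], C_pt[2]),
                    side = side)
  }
  post_ys <- slice_ys[posterior_flags]
  slm <- list(right = lapply(post_ys, mk_lm, side = "right"),
              left = lapply(post_ys, mk_lm, side = "left"))
  seed_pt <- c(geo$x_med + s * geo$obl_w / 2, geo$obl_z_lo + s * geo$obl_h / 2)
  mk_ant <- function(y, side) {
    flip <- if (side == "right") 1 else -1
    list(y_mm = y,
         refs = intensity_references(csf_mean = intensities[["csf"]],
                                     md_mean = intensities[["md"]],
                                     seed = c(flip * seed_pt[1], seed_pt[2])))
  }
  ant_ys <- slice_ys[!posterior_flags]
  ant <- list(right = lapply(ant_ys, mk_ant, side = "right"),
              left = lapply(ant_ys, mk_ant, side = "left"))

  labels <- hab_volume(lab, affine)
  attr(labels, "label_table") <- PHANTOM_LABELS
  out <- list(
    image = hab_volume(img, affine),
    labels = labels,
    acpc = acpc_landmarks(geo$ac, geo$pc, geo$midsagittal),
    slice_landmarks = slm,
    anterior = ant,
    true_masks = list(left = hab_mask(mask_l, affine, label = "left_habenula"),
                      right = hab_mask(mask_r, affine, label = "right_habenula")),
    true_volumes = c(left = sum(mask_l) * vv, right = sum(mask_r) * vv),
    params = list(grid_shape = grid_shape, voxel_size = vs,
                  habenula_volume_target = habenula_volume_target,
                  ap_extent = ap_extent, intensities = intensities,
                  noise_sigma = noise_sigma, seed = seed, scale = s,
                  posterior_y = geo$y_post, anterior_y = geo$y_ant))
  class(out) <- "hab_phantom"
  out
}

#' @export
print.hab_phantom <- function(x, ...) {
  cat(sprintf("<hab_phantom> %s voxels at %.2f mm; true volumes L %.1f / R %.1f mm^3\n",
              paste(x$params$grid_shape, collapse = "x"), x$params$voxel_size,
              x$true_volumes[["left"]], x$true_volumes[["right"]]))
  invisible(x)
}

#' Simulate a human rater's tracing of a ground-truth mask
#'
#' Perturbs the mask slice-by-slice with a smooth random boundary
#' displacement field (standard deviation `boundary_sd`, correlation length
#' about 1.5 mm) plus a systematic dilation (`bias > 0`) or erosion
#' (`bias < 0`), applied as a level-set shift of the signed Euclidean
#' distance to the boundary. Each output slice is reduced to the connected
#' component overlapping the truth, so the tracing stays connected per
#' slice. Deterministic given the seed.
#'
#' @param truth a [hab_mask()].
#' @param boundary_sd boundary displacement SD, mm (>= 0).
#' @param bias systematic boundary shift, mm (positive dilates).
#' @param seed integer seed.
#' @return A binary [hab_mask()] on the truth's grid.
#' @export
simulate_rater <- function(truth, boundary_sd, bias = 0, seed) {
  if (missing(seed)) stop("seed is required")
  if (boundary_sd < 0) stop("boundary_sd must be non-negative")
  set.seed(as.integer(seed))
  dm <- dim(truth$data)
  vs_in <- mean(truth$voxel_dims[c(1, 3)])
  out <- array(0, dim = dm)
  for (j in seq_len(dm[2])) {
    m <- truth$data[, j, ]
    if (sum(m) == 0) next
    sdt <- (EBImage::distmap(m) - EBImage::distmap(1 - m)) * vs_in
    field <- 0
    if (boundary_sd > 0) {
      f <- array(rnorm(prod(dim(m))), dim = c(dim(m), 1L))
      f <- smooth_array(f, c(1.5 / vs_in, 1.5 / vs_in, 0))[, , 1]
      field <- f / sd(f) * boundary_sd
    }
    sl <- (sdt + bias + field) > -1e-9
    if (any(sl)) {
      cc <- EBImage::bwlabel(array(as.double(sl), dim = dim(sl)))
      overlap <- tabulate(cc[m == 1 & cc > 0])
      keep <- if (length(overlap) && max(overlap) > 0) which.max(overlap)
              else which.max(tabulate(cc[cc > 0]))
      sl <- cc == keep
    }
    out[, j, ] <- as.double(sl)
  }
  if (sum(out) == 0) {
    warning("perturbation annihilated the mask; retaining the truth's central voxel")
    ctr <- round(colMeans(foreground_indices(truth)))
    out[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1] <- 1
  }
  hab_mask(out, truth$affine, label = truth$label)
}

#' Slice-span simulation for a slab-partitioned axis
#'
#' Draws anterior-posterior extents uniformly from a range, places each at a
#' uniform random offset against a contiguous grid of coronal slabs of the
#' given thickness, and counts how many slabs each extent intersects
#' (half-open slabs: an extent ending exactly on a slab boundary does not
#' enter the next slab).
#'
#' @param ap_extent_range length-2 extent interval, mm.
#' @param slice_thickness slab thickness, mm (default 0.77).
#' @param n_draws number of random placements (default 1000).
#' @param seed integer seed.
#' @return A list with `min_span`, `max_span` and the integer vector
#'   `spans`.
#' @export
slice_span_simulation <- function(ap_extent_range, slice_thickness = 0.77,
                                  n_draws = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(length(ap_extent_range) == 2, all(ap_extent_range > 0), n_draws >= 1)
  set.seed(as.integer(seed))
  e <- stats::runif(n_draws, ap_extent_range[1], ap_extent_range[2])
  o <- stats::runif(n_draws, 0, slice_thickness)
  spans <- as.integer(ceiling((o + e) / slice_thickness) - floor(o / slice_thickness))
  list(min_span = min(spans), max_span = max(spans), spans = spans)
}
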