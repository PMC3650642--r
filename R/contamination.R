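# Gaussian-smoothing contamination: how much of the post-smoothing signal
# inside a small ROI originated from surrounding structures. Smoothing
# kernels commonly applied in group fMRI analyses (5-10 mm FWHM) are larger
# than the ~30 mm^3 habenula itself, so atlas-coordinate signal can include
# substantial components from the MD thalamus and other neighbours.

#' Convert Gaussian FWHM to standard deviation
#' @param fwhm full-width at half-maximum, mm.
#' @return `fwhm / sqrt(8 * log(2))`, mm.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

# Truncated, renormalized 1D Gaussian kernel in voxel units.
gauss_kernel <- function(sigma_vox) {
  r <- as.integer(ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve along the first array axis with edge renormalization: near the
# grid boundary the kernel is truncated to in-bounds support and rescaled to
# unit sum, so constant arrays are exactly invariant.
conv_axis1 <- function(arr, k) {
  dm <- dim(arr)
  m <- dm[1]
  r <- (length(k) - 1L) %/% 2L
  A <- matrix(arr, nrow = m)
  out <- matrix(0, nrow = m, ncol = ncol(A))
  norm <- numeric(m)
  for (d in -r:r) {
    w <- k[d + r + 1L]
    i <- max(1L, 1L - d):min(m, m - d)    # output rows with in-bounds source
    out[i, ] <- out[i, ] + w * A[i + d, , drop = FALSE]
    norm[i] <- norm[i] + w
  }
  array(out / norm, dim = dm)
}

smooth_array <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    if (sigma_vox[axis] > 0) {
      k <- gauss_kernel(sigma_vox[axis])
      perm <- c(axis, setdiff(1:3, axis))
      arr <- aperm(conv_axis1(aperm(arr, perm), k), order(perm))
    }
  }
  arr
}

#' Gaussian-smooth a volume
#'
#' Separable Gaussian convolution specified in world millimetres: the
#' per-axis standard deviation in voxels is `fwhm_to_sigma(fwhm)` divided by
#' that axis's voxel size, so anisotropic grids are handled. The kernel is
#' truncated at 4 standard deviations and renormalized at grid edges
#' (normalized convolution over zero padding), so it is exactly unit-sum
#' everywhere and constant images are invariant. `fwhm = 0` returns the
#' input unchanged.
#'
#' @param vol a `hab_volume`.
#' @param fwhm isotropic kernel full-width at half-maximum, mm (>= 0).
#' @return The smoothed `hab_volume`.
#' @export
gaussian_smooth <- function(vol, fwhm) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (fwhm == 0) return(vol)
  sigma_vox <- fwhm_to_sigma(fwhm) / vol$voxel_dims
  hab_volume(smooth_array(vol$data, sigma_vox), vol$affine)
}

resolve_label <- function(labels, target_label) {
  lt <- attr(labels, "label_table")
  if (is.character(target_label)) {
    if (is.null(lt) || !(target_label %in% lt$name))
      stop("unknown label name: ", target_label)
    lt$code[match(target_label, lt$name)]
  } else as.integer(target_label)
}

#' Fraction of smoothed ROI signal originating outside the ROI
#'
#' Sets unit intensity on every labelled non-target voxel, zero on the
#' target and on unlabelled background, applies Gaussian smoothing, and
#' averages over the target mask the per-voxel share of post-smoothing
#' "signal" that emanated from surrounding structures: the smoothed
#' outside-tissue indicator divided by the smoothed all-tissue indicator.
#' The fraction is defined purely from labelled tissue (unlabelled
#' background carries no signal and does not dilute it), so for kernels
#' much larger than the target it approaches the complement's local volume
#' share of the tissue. It is signal-agnostic and upper-bounds mixing
#' independent of effect sizes.
#'
#' @param labels a `hab_volume` whose data are integer label codes
#'   (0 = background), optionally carrying a `label_table` attribute
#'   (data.frame `code`, `name`) as produced by [generate_phantom()].
#' @param target_label label name or integer code of the ROI.
#' @param fwhm smoothing kernel FWHM, mm (>= 0).
#' @return Contamination fraction in `[0, 1]`; exactly 0 at `fwhm = 0`.
#' @export
contamination_fraction <- function(labels, target_label, fwhm) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  code <- resolve_label(labels, target_label)
  lab <- labels$data
  target <- lab == code
  if (!any(target)) stop("target label absent from the label map")
  if (fwhm == 0) return(0)
  sigma_vox <- fwhm_to_sigma(fwhm) / labels$voxel_dims
  src <- array(as.double(lab != 0 & lab != code), dim = dim(lab))
  tissue <- array(as.double(lab != 0), dim = dim(lab))
  sm_src <- smooth_array(src, sigma_vox)
  sm_tis <- smooth_array(tissue, sigma_vox)
  mean(sm_src[target] / sm_tis[target])
}

#' Contamination as a function of kernel width
#'
#' @inheritParams contamination_fraction
#' @param fwhm_list non-negative kernel widths, mm, sorted ascending.
#' @return A data.frame with columns `fwhm` and `fraction`.
#' @export
contamination_curve <- function(labels, target_label, fwhm_list) {
  if (any(fwhm_list < 0)) stop("fwhm values must be non-negative")
  if (is.unsorted(fwhm_list)) stop("fwhm_list must be sorted ascending")
  data.frame(fwhm = fwhm_list,
             fraction = vapply(fwhm_list, function(f)
               contamination_fraction(labels, target_label, f), double(1)))
}
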