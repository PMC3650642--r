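# Shared fixtures and independent oracles.

# Small noise-free default phantom, generated once per test run.
default_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generate_phantom(seed = 42, noise_sigma = 0)
    ph
  }
})

# Random proper rigid motion (rotation via QR of a Gaussian matrix, with the
# sign fixed to det +1).
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, rnorm(3, sd = 10))
}

# Brute-force point-in-triangle via barycentric coordinates (inclusive),
# scalar implementation independent of the package's half-plane rasterizer.
oracle_in_triangle <- function(p, tri) {
  T <- cbind(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
  l <- solve(T, p - tri[1, ])
  l[1] >= -1e-9 && l[2] >= -1e-9 && sum(l) <= 1 + 1e-9
}

# Exhaustive sweep: 0-based (i, k) in-plane indices of all grid points whose
# centres fall inside the triangle.
oracle_raster_sweep <- function(tri, xs, zs) {
  hits <- matrix(numeric(0), 0, 2)
  for (i in seq_along(xs)) for (k in seq_along(zs)) {
    if (oracle_in_triangle(c(xs[i], zs[k]), tri))
      hits <- rbind(hits, c(i - 1L, k - 1L))
  }
  hits
}

# Brute-force ICC(2,1) from explicit double loops over cells.
oracle_icc_2_1 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + x[i, j]
  grand <- grand / (n * k)
  rm <- numeric(n); cm <- numeric(k)
  for (i in 1:n) { for (j in 1:k) rm[i] <- rm[i] + x[i, j]; rm[i] <- rm[i] / k }
  for (j in 1:k) { for (i in 1:n) cm[j] <- cm[j] + x[i, j]; cm[j] <- cm[j] / n }
  ssr <- 0; ssc <- 0; sse <- 0
  for (i in 1:n) ssr <- ssr + k * (rm[i] - grand)^2
  for (j in 1:k) ssc <- ssc + n * (cm[j] - grand)^2
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (x[i, j] - rm[i] - cm[j] + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Dense direct-convolution contamination oracle: for each target voxel,
# gather the truncated 3D Gaussian over the in-bounds support and form the
# outside-tissue / all-tissue ratio, by explicit summation.
oracle_contamination <- function(labels, target_code, fwhm) {
  lab <- labels$data
  dm <- dim(lab)
  sigma <- habseg::fwhm_to_sigma(fwhm) / labels$voxel_dims
  r <- as.integer(ceiling(4 * sigma))
  tgt <- which(lab == target_code, arr.ind = TRUE)
  src <- (lab != 0 & lab != target_code)
  tis <- (lab != 0)
  kx <- exp(-((-r[1]:r[1])^2) / (2 * sigma[1]^2))
  ky <- exp(-((-r[2]:r[2])^2) / (2 * sigma[2]^2))
  kz <- exp(-((-r[3]:r[3])^2) / (2 * sigma[3]^2))
  fracs <- numeric(nrow(tgt))
  for (t in seq_len(nrow(tgt))) {
    i0 <- tgt[t, 1]; j0 <- tgt[t, 2]; k0 <- tgt[t, 3]
    ii <- max(1, i0 - r[1]):min(dm[1], i0 + r[1])
    jj <- max(1, j0 - r[2]):min(dm[2], j0 + r[2])
    kk <- max(1, k0 - r[3]):min(dm[3], k0 + r[3])
    w <- outer(outer(kx[ii - i0 + r[1] + 1], ky[jj - j0 + r[2] + 1]),
               kz[kk - k0 + r[3] + 1])
    w <- w / sum(w)
    fracs[t] <- sum(w * src[ii, jj, kk]) / sum(w * tis[ii, jj, kk])
  }
  mean(fracs)
}

# Slab-intersection count for a segment [offset, offset + extent) against
# contiguous slabs of a given thickness (independent counting loop).
oracle_slab_count <- function(offset, extent, thickness) {
  n <- 0L; s <- 0L
  repeat {
    slab_lo <- s * thickness; slab_hi <- (s + 1) * thickness
    if (slab_lo >= offset + extent) break
    if (slab_hi > offset) n <- n + 1L
    s <- s + 1L
  }
  n
}

tmp_nii <- function() tempfile(fileext = ".nii.gz")
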