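test_that("apex construction solves the two-line intersection", {
  lm <- slice_landmarks(-24.5, A = c(0, 0), B = c(0.5, 2), C = c(4.5, -6), side = "right")
  expect_equal(apex_from_landmarks(lm), c(1.5, 0))

  # C already at A's height: apex is C itself
  lm2 <- slice_landmarks(-24.5, A = c(0, 0), B = c(1, 1), C = c(2, 0), side = "right")
  expect_equal(apex_from_landmarks(lm2), c(2, 0))

  # horizontal B-C line never reaches A's height
  lm3 <- slice_landmarks(-24.5, A = c(0, 0), B = c(1, 1), C = c(3, 1), side = "right")
  expect_error(apex_from_landmarks(lm3), "no intersection")

  # apex medial to A
  lm4 <- slice_landmarks(-24.5, A = c(3, 0), B = c(3.2, 2), C = c(2.5, -2), side = "right")
  expect_error(apex_from_landmarks(lm4), "not lateral")
})

test_that("posterior polygon has the stated vertices and shoelace area", {
  lm <- slice_landmarks(-24.5, A = c(0, 0), B = c(0.5, 2), C = c(4.5, -6), side = "right")
  poly <- posterior_slice_polygon(lm)
  expect_equal(unname(poly$vertices),
               rbind(c(0, 0), c(0.5, 2), c(1.5, 0)), tolerance = 1e-12)
  expect_equal(poly$area_mm2, 1.5)

  # mirrored left-side landmarks give a mirrored polygon of identical area
  lml <- slice_landmarks(-24.5, A = c(0, 0), B = c(-0.5, 2), C = c(-4.5, -6), side = "left")
  pl <- posterior_slice_polygon(lml)
  expect_equal(pl$area_mm2, poly$area_mm2)
  expect_equal(unname(pl$vertices[, 1]), -unname(poly$vertices[, 1]))

  # coincident landmarks violate the constructor invariant
  expect_error(slice_landmarks(-24.5, A = c(0, 0), B = c(0, 0), C = c(4, -6), "right"),
               "degenerate")
})

test_that("rasterization equals the exhaustive point-in-polygon sweep", {
  aff <- diag(c(0.77, 0.77, 0.77, 1)); aff[1:3, 4] <- c(-6.16, -26, -6.16)
  vol <- hab_volume(array(0, dim = c(17, 5, 17)), aff)
  xs <- aff[1, 4] + 0.77 * (0:16)
  zs <- aff[3, 4] + 0.77 * (0:16)
  set.seed(31)
  mismatches <- 0
  for (rep in 1:30) {
    A <- c(runif(1, -4, 0), runif(1, -4, 0))
    B <- A + c(runif(1, 0, 1.5), runif(1, 0.5, 5))
    C <- B + c(runif(1, 1, 8), -runif(1, 1.5, 9))
    lm <- suppressWarnings(try(slice_landmarks(-24.5, A, B, C, side = "right"), silent = TRUE))
    if (inherits(lm, "try-error")) next
    poly <- try(posterior_slice_polygon(lm), silent = TRUE)
    if (inherits(poly, "try-error")) next
    mask <- suppressWarnings(rasterize_polygon(poly, vol))
    got <- foreground <- which(mask$data == 1, arr.ind = TRUE)
    got <- got[, c(1, 3), drop = FALSE] - 1L
    want <- oracle_raster_sweep(poly$vertices, xs, zs)
    mismatches <- mismatches +
      (nrow(got) != nrow(want) || (nrow(got) > 0 && !all(got[order(got[, 1], got[, 2]), ] ==
                                                          want[order(want[, 1], want[, 2]), ])))
  }
  expect_equal(mismatches, 0)
})

test_that("voxel count converges to the area ratio under scaling on a fine grid", {
  # 0.1 mm grid: doubling the polygon in both in-plane axes ~ quadruples the count
  aff <- diag(c(0.1, 0.77, 0.1, 1)); aff[1:3, 4] <- c(-10, -25, -10)
  vol <- hab_volume(array(0, dim = c(200, 3, 200)), aff)
  lm1 <- slice_landmarks(-25, A = c(0, 0), B = c(0.5, 2), C = c(4.5, -6), side = "right")
  lm2 <- slice_landmarks(-25, A = c(0, 0), B = c(1, 4), C = c(9, -12), side = "right")
  n1 <- sum(rasterize_polygon(posterior_slice_polygon(lm1), vol)$data)
  n2 <- sum(rasterize_polygon(posterior_slice_polygon(lm2), vol)$data)
  expect_lt(abs(n2 / n1 - 4), 0.4)
})

test_that("mirror symmetry: reflected landmarks give the mirror-image mask", {
  # grid symmetric about x = 0 so reflection maps voxel centres to centres
  aff <- diag(c(0.77, 0.77, 0.77, 1)); aff[1:3, 4] <- c(-0.77 * 10.5, -26, -5)
  vol <- hab_volume(array(0, dim = c(22, 5, 17)), aff)
  lm_r <- slice_landmarks(-24.5, A = c(1, 1), B = c(1.5, 4.5), C = c(8, -2), side = "right")
  lm_l <- slice_landmarks(-24.5, A = c(-1, 1), B = c(-1.5, 4.5), C = c(-8, -2), side = "left")
  mr <- rasterize_polygon(posterior_slice_polygon(lm_r), vol)$data
  ml <- rasterize_polygon(posterior_slice_polygon(lm_l), vol)$data
  expect_identical(ml, mr[dim(mr)[1]:1, , ])
})

test_that("anterior region growing recovers the phantom's oblong exactly", {
  ph <- default_phantom()
  a <- ph$anterior$right[[1]]
  roi <- anterior_slice_roi(ph$image, a$y_mm, a$refs, side = "right")
  j <- habseg:::y_to_slice(ph$image, a$y_mm)
  truth_slice <- ph$true_masks$right$data[, j + 1, ]
  expect_identical(roi$data[, j + 1, ], truth_slice)
  expect_equal(sum(roi$data), sum(roi$data[, j + 1, ]))  # single slice
})

test_that("anterior region growing flags inverted contrast and leakage", {
  ph <- default_phantom()
  a <- ph$anterior$right[[1]]
  # seed in the third-ventricle CSF: darker than MD
  refs_csf <- intensity_references(0.3, 1.0, seed = c(0, 2))
  expect_warning(roi <- anterior_slice_roi(ph$image, a$y_mm, refs_csf, side = "right"),
                 "inverted contrast")
  expect_equal(sum(roi$data), 1)

  # uniform image: no boundary exists anywhere
  uni <- hab_volume(array(1.3, dim = dim(ph$image$data)), ph$image$affine)
  expect_error(anterior_slice_roi(uni, a$y_mm, a$refs, side = "right"), "leakage")
})

test_that("intensity reference invariants hold", {
  expect_error(intensity_references(1.0, 0.3, c(3, 2)), "csf_mean must be <")
})

test_that("assemble_roi validates contiguity and slice span", {
  ph <- default_phantom()
  vol <- ph$image
  mk_slice <- function(y) {
    lm <- slice_landmarks(y, A = c(1, 1), B = c(1.5, 4.5), C = c(8, -2), side = "right")
    rasterize_polygon(posterior_slice_polygon(lm), vol)
  }
  ys <- voxel_to_world(vol, c(0, 20, 0))[2] + 0.77 * (0:3)
  roi <- assemble_roi(lapply(ys, mk_slice))
  expect_equal(attr(roi, "slice_span"), 4L)
  expect_equal(slice_span(roi, "y"), 4L)

  expect_warning(assemble_roi(lapply(ys[1:2], mk_slice)), "expected 3-5")
  expect_error(assemble_roi(lapply(ys[c(1, 3)], mk_slice)), "gap")
  expect_error(assemble_roi(lapply(ys, mk_slice), posterior_y = ys[2], anterior_y = ys[4]),
               "posterior")
})

test_that("ambiguous medial voxels can be folded in, bounded by intensity", {
  ph <- default_phantom()
  m <- ph$true_masks$right
  aug <- include_ambiguous_medial(m, ph$image, csf_mean = 0.3, side = "right")
  expect_gte(sum(aug$data), sum(m$data))
  added <- which(aug$data == 1 & m$data == 0)
  if (length(added)) {
    vals <- ph$image$data[added]
    expect_true(all(vals > 0.3 & vals < mean(ph$image$data[m$data == 1])))
  }
})
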