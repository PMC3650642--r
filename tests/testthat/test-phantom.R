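test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(seed = 7)
  b <- generate_phantom(seed = 7)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$true_volumes, b$true_volumes)
  c <- generate_phantom(seed = 8)
  expect_false(identical(a$image$data, c$image$data))  # noise differs
})

test_that("ground-truth volume hits the target within one voxel volume", {
  ph <- default_phantom()
  vv <- ph$params$voxel_size^3
  expect_lt(abs(ph$true_volumes[["right"]] - 30), vv)
  expect_lt(abs(ph$true_volumes[["left"]] - 30), vv)
  expect_equal(mask_volume(ph$true_masks$right), ph$true_volumes[["right"]])
})

test_that("phantom anatomy satisfies the label-map invariants", {
  ph <- default_phantom()
  lab <- ph$labels$data
  l <- lab == 3L; r <- lab == 4L
  expect_equal(sum(l & r), 0)

  # a CSF column separates the sides at the midline
  X <- array(habseg::voxel_to_world(ph$labels, cbind(0:(dim(lab)[1] - 1), 0, 0))[, 1],
             dim = dim(lab))
  expect_true(all(lab[abs(X) < 1 & (l | r)] == 0))     # no habenula at the midline
  mid <- abs(X) < ph$params$voxel_size
  expect_true(any(lab[mid] == 1L))                     # ventricle CSF present

  # each habenula touches CSF medially and MD laterally (check via x-neighbours)
  nbr_lower_x <- function(m) {              # voxels whose +x neighbour is in m
    out <- array(FALSE, dim = dim(m))
    out[1:(dim(m)[1] - 1), , ] <- m[2:dim(m)[1], , ]
    out
  }
  nbr_upper_x <- function(m) {              # voxels whose -x neighbour is in m
    out <- array(FALSE, dim = dim(m))
    out[2:dim(m)[1], , ] <- m[1:(dim(m)[1] - 1), , ]
    out
  }
  expect_true(any(lab[nbr_lower_x(r)] == 1L))   # medial (-x) neighbour of right is CSF
  expect_true(any(lab[nbr_upper_x(r)] == 2L))   # lateral (+x) neighbour is MD
  expect_true(any(lab[nbr_upper_x(l)] == 1L))   # medial (+x) neighbour of left is CSF
  expect_true(any(lab[nbr_lower_x(l)] == 2L))   # lateral (-x) neighbour is MD
})

test_that("habenula is brighter than MD in every voxel at zero noise", {
  ph <- default_phantom()
  hab_vals <- ph$image$data[ph$labels$data %in% c(3L, 4L)]
  md_mean <- mean(ph$image$data[ph$labels$data == 2L])
  expect_true(all(hab_vals > md_mean))
})

test_that("phantom landmarks satisfy the delineation invariants", {
  ph <- default_phantom()
  for (side in c("left", "right")) {
    for (lm in ph$slice_landmarks[[side]]) {
      expect_s3_class(lm, "hab_slice_landmarks")
      apex <- apex_from_landmarks(lm)
      expect_equal(apex[2], lm$A[2])
      expect_gt(abs(apex[1]), abs(lm$A[1]))
    }
  }
  expect_error(generate_phantom(grid_shape = c(16, 16, 16), seed = 1), "too small")
})

test_that("tracing the phantom with its own landmarks recovers the true volume", {
  ph <- default_phantom()
  for (side in c("left", "right")) {
    m <- delineate_habenula(ph$image, ph$slice_landmarks[[side]],
                            anterior = ph$anterior[[side]],
                            posterior_y = ph$params$posterior_y,
                            anterior_y = ph$params$anterior_y)
    v <- mask_volume(m)
    truth <- ph$true_volumes[[side]]
    expect_lt(abs(v - truth) / truth, 0.15)
  }
})

test_that("delineation error shrinks with resolution", {
  fine <- generate_phantom(grid_shape = c(104, 168, 84), voxel_size = 0.3,
                           noise_sigma = 0, seed = 9)
  m <- delineate_habenula(fine$image, fine$slice_landmarks$right,
                          anterior = fine$anterior$right)
  expect_lt(abs(mask_volume(m) - fine$true_volumes[["right"]]) /
              fine$true_volumes[["right"]], 0.05)
})

test_that("simulated raters reduce to the truth at zero perturbation", {
  ph <- default_phantom()
  r0 <- simulate_rater(ph$true_masks$right, boundary_sd = 0, bias = 0, seed = 3)
  expect_identical(r0$data, ph$true_masks$right$data)

  rd <- simulate_rater(ph$true_masks$right, boundary_sd = 0, bias = 0.77, seed = 3)
  expect_gt(mask_volume(rd), mask_volume(ph$true_masks$right))

  ra <- simulate_rater(ph$true_masks$right, boundary_sd = 0.4, bias = 0, seed = 3)
  rb <- simulate_rater(ph$true_masks$right, boundary_sd = 0.4, bias = 0, seed = 3)
  expect_identical(ra$data, rb$data)                 # deterministic given seed
  expect_true(all(ra$data %in% c(0, 1)))

  # strong erosion annihilates the mask: warning, central voxel retained
  expect_warning(rz <- simulate_rater(ph$true_masks$right, 0, bias = -20, seed = 3),
                 "annihilated")
  expect_equal(sum(rz$data), 1)
})

test_that("slab-intersection simulation matches the analytic counting oracle", {
  # extent exactly two slabs wide, zero offset: occupies exactly 2 slabs
  expect_equal(oracle_slab_count(0, 1.54, 0.77), 2L)
  sim0 <- slice_span_simulation(c(1.54, 1.54), 0.77, n_draws = 1, seed = 1)
  set.seed(1)
  e <- runif(1, 1.54, 1.54); o <- runif(1, 0, 0.77)
  expect_equal(sim0$spans[1], oracle_slab_count(o, e, 0.77))

  sim <- slice_span_simulation(c(2.0, 3.0), 0.77, n_draws = 200, seed = 5)
  set.seed(5)
  e <- runif(200, 2, 3); o <- runif(200, 0, 0.77)
  want <- mapply(oracle_slab_count, o, e, 0.77)
  expect_equal(sim$spans, as.integer(want))
})

test_that("halving slab thickness roughly doubles the span", {
  a <- slice_span_simulation(c(2.0, 3.0), 0.77, n_draws = 500, seed = 6)
  b <- slice_span_simulation(c(2.0, 3.0), 0.385, n_draws = 500, seed = 6)
  expect_gte(b$min_span, 2 * a$min_span - 1)
  expect_lte(b$max_span, 2 * a$max_span)
})

test_that("default phantom volumes traced end-to-end fall in the plausible adult range", {
  ph <- default_phantom()
  for (side in c("left", "right")) {
    m <- delineate_habenula(ph$image, ph$slice_landmarks[[side]],
                            anterior = ph$anterior[[side]])
    v <- mask_volume(m)
    expect_gte(v, 21.2); expect_lte(v, 37.2)
  }
})
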