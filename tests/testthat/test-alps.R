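alps_maps_const <- function(dims, dxx, dyy, dzz) {
  list(Dxx = array(dxx, dims), Dyy = array(dyy, dims),
       Dzz = array(dzz, dims))
}

test_that("ALPS index is exactly 1 for an isotropic diffusivity field", {
  dims <- c(10, 10, 10)
  m <- alps_maps_const(dims, 0.8e-3, 0.8e-3, 0.8e-3)
  rois <- make_alps_phantom_rois(dims)
  res <- compute_alps(m$Dxx, m$Dyy, m$Dzz, rois)
  expect_equal(res$alps_index, 1, tolerance = 1e-12)
})

test_that("hand-computed ratio is reproduced on single-voxel ROIs", {
  dims <- c(5, 5, 5)
  Dxx <- array(0, dims); Dyy <- array(0, dims); Dzz <- array(0, dims)
  proj <- matrix(c(2, 2, 2), 1); assoc <- matrix(c(2, 4, 2), 1)
  Dxx[2, 2, 2] <- 1.2e-3; Dxx[2, 4, 2] <- 1.4e-3
  Dyy[2, 2, 2] <- 0.8e-3; Dyy[2, 4, 2] <- 9    # assoc Dyy unused
  Dzz[2, 4, 2] <- 0.6e-3; Dzz[2, 2, 2] <- 9    # proj Dzz unused
  res <- compute_alps(Dxx, Dyy, Dzz, alps_roi(proj, assoc))
  expect_equal(res$alps_index, mean(c(1.2, 1.4)) / mean(c(0.8, 0.6)),
               tolerance = 1e-12)
  expect_equal(res$alps_index, 1.3 / 0.7, tolerance = 1e-12)
})

test_that("the index is scale invariant and monotone in Dxx_proj", {
  dims <- c(10, 10, 10)
  set.seed(1)
  Dxx <- array(runif(prod(dims), 0.5, 1.5) * 1e-3, dims)
  Dyy <- array(runif(prod(dims), 0.5, 1.5) * 1e-3, dims)
  Dzz <- array(runif(prod(dims), 0.5, 1.5) * 1e-3, dims)
  rois <- make_alps_phantom_rois(dims)
  base <- compute_alps(Dxx, Dyy, Dzz, rois)$alps_index
  scaled <- compute_alps(Dxx * 7, Dyy * 7, Dzz * 7, rois)$alps_index
  expect_equal(scaled, base, tolerance = 1e-12)

  Dxx2 <- Dxx
  Dxx2[rois$proj] <- Dxx2[rois$proj] + 0.5e-3
  expect_gt(compute_alps(Dxx2, Dyy, Dzz, rois)$alps_index, base)
})

test_that("bilateral index is the mean of unilateral indices", {
  dims <- c(12, 12, 12)
  set.seed(2)
  Dxx <- array(runif(prod(dims), 0.5, 1.5) * 1e-3, dims)
  Dyy <- array(runif(prod(dims), 0.5, 1.5) * 1e-3, dims)
  Dzz <- array(runif(prod(dims), 0.5, 1.5) * 1e-3, dims)
  left <- make_alps_phantom_rois(dims, offset = c(-3, 1, 1))
  right <- make_alps_phantom_rois(dims, offset = c(2, 1, 1))
  bi <- compute_alps(Dxx, Dyy, Dzz, list(left, right))
  il <- compute_alps(Dxx, Dyy, Dzz, left)$alps_index
  ir <- compute_alps(Dxx, Dyy, Dzz, right)$alps_index
  expect_equal(bi$alps_index, mean(c(il, ir)), tolerance = 1e-12)
})

test_that("ROI guards: disjointness, emptiness, bounds, determinism", {
  dims <- c(10, 10, 10)
  expect_identical(make_alps_phantom_rois(dims),
                   make_alps_phantom_rois(dims))
  expect_error(make_alps_phantom_rois(c(3, 3, 3), roi_size = 4), "too small")
  v <- matrix(c(1, 1, 1), 1)
  expect_error(alps_roi(v, v), "disjoint")
  expect_error(alps_roi(v[0, , drop = FALSE], v), "nonempty")

  # all-NA ROI voxels are an error; negative values clamp with a warning
  Dxx <- array(1e-3, dims); Dxx[1, 1, 1] <- NA
  Dyy <- array(1e-3, dims); Dzz <- array(1e-3, dims)
  r <- alps_roi(matrix(c(1, 1, 1), 1), matrix(c(2, 1, 1), 1))
  expect_error(compute_alps(Dxx, Dyy, Dzz, r), "no finite")
  Dxx[1, 1, 1] <- -1e-3
  expect_warning(res <- compute_alps(Dxx, Dyy, Dzz, r), "clamped")
  expect_equal(res$Dxx_proj, 0)
})
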