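tube_mask <- function(dims, x, y, zrange) {
  m <- array(FALSE, dims)
  m[x, y, zrange] <- TRUE
  m
}

test_that("component labeling partitions the mask deterministically", {
  dims <- c(8, 8, 8)
  m <- tube_mask(dims, 2, 2, 2:4) | tube_mask(dims, 6, 6, 3:5)
  comp <- label_components(m, spacing = c(1, 1, 1))
  expect_equal(nrow(comp), 2L)
  vox <- attr(comp, "voxels")
  expect_equal(sum(vapply(vox, nrow, 0L)), sum(m))
  all_vox <- do.call(rbind, vox)
  expect_equal(nrow(unique(all_vox)), sum(m))          # disjoint + exhaustive
  # empty mask
  expect_equal(nrow(label_components(array(FALSE, dims))), 0L)
  # deterministic
  expect_identical(label_components(m)$volume_mm3,
                   label_components(m)$volume_mm3)
})

test_that("diagonal adjacency is connected under 26- but not 6-connectivity", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE
  expect_equal(nrow(label_components(m, connectivity = 26)), 1L)
  expect_equal(nrow(label_components(m, connectivity = 6)), 2L)
  # face-diagonal: shares an edge -> connected under 18
  m2 <- array(FALSE, c(3, 3, 3))
  m2[1, 1, 1] <- TRUE
  m2[2, 2, 1] <- TRUE
  expect_equal(nrow(label_components(m2, connectivity = 18)), 1L)
  expect_equal(nrow(label_components(m2, connectivity = 6)), 2L)
})

test_that("diameter estimation matches an analytic cylinder", {
  # radius 1.0 mm cylinder rendered at 0.5 mm spacing, axis z
  sp <- c(0.5, 0.5, 0.5)
  dims <- c(15, 15, 20)
  ctr <- c(8, 8)
  co <- arrayInd(seq_len(prod(dims)), dims)
  r2 <- ((co[, 1] - ctr[1]) * sp[1])^2 + ((co[, 2] - ctr[2]) * sp[2])^2
  m <- array(r2 <= 1.0^2 & co[, 3] >= 4 & co[, 3] <= 16, dims)
  comp <- label_components(m, spacing = sp)
  expect_equal(nrow(comp), 1L)
  expect_lt(abs(comp$diameter_mm[1] - 2.0), 0.5)     # within one voxel
  expect_gt(comp$elongation[1], 1.5)                 # clearly tubular

  # single voxel: min spacing, flagged
  d1 <- estimate_diameter(matrix(c(2, 2, 2), 1), spacing = c(0.8, 0.8, 2))
  expect_equal(d1$diameter, 0.8)
  expect_true(d1$flagged)

  # doubling the spacing doubles the diameter of the same voxel set
  vox <- attr(comp, "voxels")[[1]]
  da <- estimate_diameter(vox, spacing = sp)$diameter
  db <- estimate_diameter(vox, spacing = 2 * sp)$diameter
  expect_equal(db, 2 * da, tolerance = 1e-12)
})

test_that("false-positive filtering applies each rule with a reason", {
  dims <- c(14, 14, 14)
  # elongated tube (kept), round ball (removed), tube inside WMH (removed)
  m <- tube_mask(dims, 2, 2, 2:9)
  co <- arrayInd(seq_len(prod(dims)), dims)
  ball <- array(colSums((t(co) - c(8, 8, 8))^2) <= 2.1^2, dims)
  m <- m | ball
  wmh_tube <- tube_mask(dims, 12, 12, 3:7)
  m <- m | wmh_tube
  wmh <- array(FALSE, dims)
  wmh[12, 12, 3:5] <- TRUE                     # 60% of the 5-voxel tube

  comp <- label_components(m)
  comp <- filter_false_positives(comp, wmh)
  res <- split(comp$reason, comp$kept)
  expect_equal(sum(comp$kept), 1L)
  expect_setequal(stats::na.omit(comp$reason), c("round", "wmh_overlap"))
  kept_vox <- attr(comp, "voxels")[[which(comp$kept)]]
  expect_equal(nrow(kept_vox), 8L)             # the clean tube

  # idempotency
  again <- filter_false_positives(comp, wmh)
  expect_identical(again$kept, comp$kept)
  expect_identical(again$reason, comp$reason)

  # size gates
  tiny <- label_components(tube_mask(dims, 3, 3, 3))
  tiny <- filter_false_positives(tiny, NULL,
                                 pas_filter_config(volume_min_voxels = 2))
  expect_equal(tiny$reason, "too_small")

  # custom predicate plug-in
  comp2 <- label_components(tube_mask(dims, 2, 2, 2:9))
  comp2 <- filter_false_positives(comp2, NULL,
    pas_filter_config(predicates = list(
      anatomical_exclusion = function(row, vox) TRUE)))
  expect_equal(comp2$reason, "anatomical_exclusion")
})

test_that("ROI assignment picks the maximal overlap with documented ties", {
  dims <- c(10, 10, 10)
  m <- tube_mask(dims, 2, 2, 2:8)              # 7 voxels
  roi <- array(0L, dims)
  roi[2, 2, 2:6] <- 1L                         # 5-voxel overlap with ROI 1
  roi[2, 2, 7:8] <- 2L                         # 2-voxel overlap with ROI 2
  comp <- assign_to_rois(label_components(m), roi)
  expect_equal(comp$roi_label, 1L)
  expect_false(comp$roi_tie)

  roi2 <- array(0L, dims)
  roi2[2, 2, 2:4] <- 5L
  roi2[2, 2, 5:7] <- 3L                        # exact tie -> lowest label
  comp2 <- assign_to_rois(label_components(m), roi2)
  expect_equal(comp2$roi_label, 3L)
  expect_true(comp2$roi_tie)

  # zero overlap stays unassigned
  comp3 <- assign_to_rois(label_components(m), array(0L, dims))
  expect_true(is.na(comp3$roi_label))
})

test_that("n-largest selection is by volume with deterministic ties", {
  dims <- c(20, 8, 14)
  m <- array(FALSE, dims)
  lens <- c(10, 8, 5, 3, 1)                    # tube lengths = volumes
  for (i in seq_along(lens)) m[2 * i, 2, seq_len(lens[i]) + 1] <- TRUE
  roi <- array(1L, dims)
  comp <- select_n_largest(assign_to_rois(label_components(m), roi), n = 4)
  expect_equal(sort(comp$n_voxels[comp$selected], decreasing = TRUE),
               c(10, 8, 5, 3))
  expect_null(attr(comp, "shortfall"))

  # subset-sum optimality oracle: enumerate all size-4 subsets
  vols <- comp$volume_mm3[comp$kept]
  best <- max(combn(vols, 4, sum))
  expect_equal(sum(comp$volume_mm3[comp$selected]), best)

  # fewer than n -> all selected, shortfall recorded
  m2 <- tube_mask(c(8, 8, 8), 2, 2, 2:4)
  comp2 <- select_n_largest(assign_to_rois(label_components(m2),
                                           array(1L, c(8, 8, 8))), n = 4)
  expect_equal(sum(comp2$selected), 1L)
  expect_equal(attr(comp2, "shortfall")$n_available, 1L)

  # equal volumes: stable id order
  m3 <- tube_mask(c(12, 8, 8), 2, 2, 2:4) | tube_mask(c(12, 8, 8), 5, 2, 2:4) |
    tube_mask(c(12, 8, 8), 8, 2, 2:4)
  comp3 <- select_n_largest(assign_to_rois(label_components(m3),
                                           array(1L, c(12, 8, 8))), n = 2)
  expect_equal(comp3$id[comp3$selected], c(1L, 2L))
})
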