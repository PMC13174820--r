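make_maps <- function(dims, fwvf, fwad = fwvf) {
  maps <- stats::setNames(rep(list(array(NA_real_, dims)),
                              length(glymphr:::map_names)),
                          glymphr:::map_names)
  maps$FWVF <- fwvf
  maps$FWAD <- fwad
  glymphr:::scalar_maps(maps, c(1, 1, 1), array(1L, dims))
}

test_that("pAs ROI metrics are unweighted voxel means of selected components", {
  dims <- c(10, 10, 10)
  m <- array(FALSE, dims)
  m[2, 2, 2:3] <- TRUE                       # component with 2 voxels
  fwvf <- array(0, dims)
  fwvf[2, 2, 2] <- 0.8; fwvf[2, 2, 3] <- 0.6
  comp <- label_components(m)
  comp <- assign_to_rois(comp, array(1L, dims))
  comp <- select_n_largest(comp, n = 4)
  res <- pas_roi_metrics(make_maps(dims, fwvf), comp)
  expect_equal(res$per_roi$pas_FWVF, 0.7)
  expect_equal(res$whole_brain[["pas_FWVF"]], 0.7)

  # an ROI whose only component was filtered out is missing and reported
  m2 <- m; m2[8, 8, 2:3] <- TRUE                  # second component
  roi2 <- array(1L, dims); roi2[8, , ] <- 2L      # it sits in ROI 2
  comp2 <- assign_to_rois(label_components(m2), roi2)
  comp2$kept[comp2$roi_label == 2] <- FALSE       # removed as false positive
  comp2 <- select_n_largest(comp2)
  expect_message(res2 <- pas_roi_metrics(make_maps(dims, fwvf), comp2),
                 "without selected")
  expect_true(2 %in% res2$missing_rois)
  expect_true(is.na(res2$per_roi$pas_FWVF[res2$per_roi$roi_label == 2]))
})

test_that("WM-FWVF exclusion masks are respected exactly", {
  dims <- c(8, 8, 8)
  fwvf <- array(0.1, dims)
  pas <- array(FALSE, dims); pas[4, 4, 4:5] <- TRUE
  wmh <- array(FALSE, dims); wmh[2, 2, 2] <- TRUE
  fwvf[pas] <- 0.9                            # contamination to be excluded
  fwvf[wmh] <- 0.7
  wm <- array(TRUE, dims)
  res <- wm_fwvf(make_maps(dims, fwvf), wm, wmh, pas, array(1L, dims))
  expect_equal(res$whole_brain, 0.1, tolerance = 1e-12)
  expect_equal(res$per_roi$wm_FWVF, 0.1, tolerance = 1e-12)
  # voxel bookkeeping: excluded voxels do not contribute
  expect_equal(res$per_roi$n_voxels, sum(wm) - 3L)

  # WMH covering a whole ROI -> missing value
  roi <- array(1L, dims); roi[1, , ] <- 2L
  wmh_all <- array(FALSE, dims); wmh_all[1, , ] <- TRUE
  res2 <- wm_fwvf(make_maps(dims, fwvf), wm, wmh_all, pas, roi)
  expect_true(is.na(res2$per_roi$wm_FWVF[res2$per_roi$roi_label == 2]))

  # no exclusions -> plain ROI mean
  res3 <- wm_fwvf(make_maps(dims, array(0.25, dims)), wm)
  expect_equal(res3$whole_brain, 0.25)
})

test_that("feature sets have the documented shapes and deletion policy", {
  coh <- make_cohort(cohort_spec(n = 60), seed = 4)
  feats <- coh$features
  pet_cols <- grep("suvr", names(feats), value = TRUE)
  pet <- feats[, pet_cols]
  feats <- feats[, setdiff(names(feats), pet_cols)]
  sets <- build_feature_sets(feats, pet = NULL)
  expect_equal(ncol(sets$pas), 6L)
  expect_equal(ncol(sets$wm), 3L)
  expect_equal(ncol(sets$pvs), 1L)
  expect_equal(ncol(sets$pas_wm), 9L)
  expect_equal(ncol(sets$all), 10L)

  sets_pet <- build_feature_sets(feats, pet = pet)
  expect_equal(ncol(sets_pet$abeta_pet), 3L)
  expect_equal(ncol(sets_pet$tau_pet), 3L)

  # subject missing only ALPS drops from pvs analyses, stays elsewhere
  feats$alps[1] <- NA
  sets2 <- build_feature_sets(feats)
  expect_false(1 %in% attr(sets2$pvs, "rows"))
  expect_true(1 %in% attr(sets2$pas, "rows"))

  expect_error(build_feature_sets(feats[, 1:3, drop = FALSE]), "absent")
})
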