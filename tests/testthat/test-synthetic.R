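test_that("Rician noise has the documented properties", {
  s <- matrix(runif(50, 50, 100), 10)
  expect_identical(add_rician_noise(s, 0), s)                 # sigma 0
  expect_identical(add_rician_noise(s, 5, seed = 3),
                   add_rician_noise(s, 5, seed = 3))          # seeded
  # zero signal: Rayleigh mean = sigma * sqrt(pi / 2)
  m <- mean(add_rician_noise(rep(0, 1e5), 10, seed = 9))
  expect_lt(abs(m - 10 * sqrt(pi / 2)) / (10 * sqrt(pi / 2)), 0.02)
  expect_error(add_rician_noise(s, -1))
})

test_that("phantom rendering is deterministic and labels partition", {
  spec <- phantom_spec(dims = c(10, 10, 8), seed = 5)
  ph1 <- render_phantom(spec, hcpa_scheme, snr = 30)
  ph2 <- render_phantom(spec, hcpa_scheme, snr = 30)
  expect_identical(ph1$dwi, ph2$dwi)

  with(ph1$masks, {
    expect_false(any(wm & pas)); expect_false(any(wm & wmh))
    expect_false(any(pas & wmh))
  })
  expect_true(any(ph1$masks$pas))
  expect_true(any(ph1$masks$wmh))
  # truth ordering: tubes carry high free water against low-FWVF WM
  expect_equal(unique(ph1$truth$FWVF[ph1$masks$pas]), 0.9)
  expect_equal(unique(ph1$truth$FWVF[ph1$masks$wm]), 0.1)
  # a blob placed onto a tube is an overlap error
  expect_error(render_phantom(phantom_spec(dims = c(7, 7, 8), n_tubes = 3,
                                           tube_radius_mm = 3,
                                           wmh_radius_mm = 5),
                              hcpa_scheme),
               "overlap")
})

test_that("zero-noise phantom voxels refit to their truth", {
  spec <- phantom_spec(dims = c(8, 8, 8))
  ph <- render_phantom(spec, hcpa_scheme)
  for (nm in c("wm", "pas")) {
    v <- which(ph$masks[[nm]])[1]
    co <- arrayInd(v, spec$dims)
    sig <- ph$dwi[co[1], co[2], co[3], ]
    fit <- fit_bitensor(sig, hcpa_scheme)
    expect_lt(abs(fit$f - spec$recipes[[nm]]$f), 0.02)
  }
})

test_that("cohort generation respects the spec and is reproducible", {
  spec <- cohort_spec(n = 120)
  c1 <- make_cohort(spec, seed = 3)
  c2 <- make_cohort(spec, seed = 3)
  expect_identical(c1$pheno, c2$pheno)
  expect_identical(c1$features, c2$features)
  expect_equal(nrow(c1$pheno), 120L)
  expect_true(all(levels(c1$pheno$diagnosis) == c("CN", "MCI", "AD")))
  expect_true(all(c1$features$pas_FWVF_precuneus >= 0 &
                    c1$features$pas_FWVF_precuneus <= 1))
  expect_equal(c1$pheno$map,
               derive_map(c1$pheno$systolic, c1$pheno$diastolic))
  expect_error(cohort_spec(group_props = c(CN = 0.5, MCI = 0.2, AD = 0.2)),
               "sum to 1")
  expect_error(cohort_spec(noise_sd = 0), "positive")
})

test_that("planted cohort effects are detectable by the analysis battery", {
  coh <- make_cohort(cohort_spec(n = 400), seed = 6)
  d <- merge(coh$features, coh$pheno, by = "subject")
  # planted negative BMI slope on whole-brain pAs-FWAD
  sb <- standardized_beta("pas_FWAD_wholebrain", "bmi", c("age", "sex"), d)
  expect_lt(sb$beta, -0.15)
  expect_lt(sb$p, 0.01)
  # null effect: total cholesterol was not planted
  sb0 <- standardized_beta("pas_FWAD_wholebrain", "total_cholesterol",
                           c("age", "sex"), d)
  expect_gt(sb0$p, 0.001)
  # planted diagnostic-group offsets on FWVF
  a <- ancova("pas_FWVF_wholebrain", "diagnosis", c("age", "sex"), d)
  expect_lt(a$p, 0.01)
})

test_that("null cohorts yield uniform association p-values", {
  set.seed(30)
  null_spec <- cohort_spec(n = 150, fwad_effects = c(bmi = 0),
                           fwvf_effects = c(age = 0),
                           fwvf_group_offset = 0)
  ps <- vapply(1:40, function(i) {
    coh <- make_cohort(null_spec, seed = 1000 + i)
    d <- merge(coh$features, coh$pheno, by = "subject")
    standardized_beta("pas_FWAD_wholebrain", "bmi", c("age", "sex"), d)$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
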