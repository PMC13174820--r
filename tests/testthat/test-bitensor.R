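test_that("forward model matches direct evaluation of the mixture formula", {
  vox <- bitensor_voxel(1, 0.5, diag(3) * 3.0e-3, diag(3) * 0.7e-3)
  s <- simulate_signal(vox, tiny_scheme(b = 1000))
  expect_equal(s[1], 1)                                   # b0 -> S0 exactly
  expect_equal(s[2], 0.5 * exp(-3) + 0.5 * exp(-0.7), tolerance = 1e-12)

  # f = 0 degenerates to the single-tensor signal of the tissue compartment
  Dt <- axial_tensor(c(0, 1, 0), 1.5e-3, 0.4e-3)
  vox0 <- bitensor_voxel(50, 0, diag(3) * 3e-3, Dt)
  B <- glymphr:::scheme_design(hcpa_scheme)
  ref <- 50 * exp(-drop(B %*% dt_vec(Dt)))
  expect_equal(simulate_signal(vox0, hcpa_scheme), ref, tolerance = 1e-12)

  # signal bounded by S0 for b > 0
  set.seed(7)
  vox <- random_truth_voxel()
  s <- simulate_signal(vox, hcpa_scheme)
  expect_true(all(s > 0 & s <= vox$S0 + 1e-12))
  expect_true(all(s[hcpa_scheme$b0] == vox$S0))
})

test_that("invalid model states are rejected", {
  expect_error(bitensor_voxel(1, 1.2, diag(3) * 3e-3, diag(3) * 1e-3),
               "f must lie")
  expect_error(bitensor_voxel(1, 0.5, diag(c(1, 1, -1)) * 1e-3,
                              diag(3) * 1e-3), "positive semi-definite")
  expect_error(bitensor_voxel(0, 0.5, diag(3) * 3e-3, diag(3) * 1e-3),
               "S0")
})

test_that("noiseless round-trip recovers the planted parameters", {
  set.seed(11)
  for (i in 1:8) {
    vox <- random_truth_voxel()
    fit <- fit_bitensor(simulate_signal(vox, hcpa_scheme), hcpa_scheme)
    expect_lt(abs(fit$f - vox$f), 0.02)
    ad_true <- tensor_metrics(vox$D_fluid)$AD
    expect_lt(abs(tensor_metrics(fit$D_fluid)$AD - ad_true) / ad_true,
              0.05)
    md_true <- tensor_metrics(vox$D_tissue)$MD
    expect_lt(abs(tensor_metrics(fit$D_tissue)$MD - md_true) / md_true,
              0.05)
  }
})

test_that("boundary fractions are recovered", {
  Dt <- axial_tensor(c(1, 0, 0), 1.4e-3, 0.4e-3)
  s_fw <- simulate_signal(bitensor_voxel(100, 1, diag(3) * 3e-3, Dt),
                          hcpa_scheme)
  expect_gte(fit_bitensor(s_fw, hcpa_scheme)$f, 0.95)
  s_t <- simulate_signal(bitensor_voxel(100, 0, diag(3) * 3e-3, Dt),
                         hcpa_scheme)
  expect_lte(fit_bitensor(s_t, hcpa_scheme)$f, 0.05)
  expect_lte(fit_isotropic_fwe(s_t, hcpa_scheme)$f, 0.05)
})

test_that("single-shell schemes are refused (identifiability guard)", {
  sch1 <- acq_scheme(c(0, rep(1000, 6)),
                     rbind(c(0, 0, 0), diag(3), -diag(3)) )
  s <- simulate_signal(random_truth_voxel(), sch1)
  expect_error(fit_bitensor(s, sch1), "two\\s+distinct|insufficient")
  expect_error(fit_isotropic_fwe(s, sch1), "two\\s+distinct|insufficient")
  expect_error(fit_bitensor(rep(-1, 96), hcpa_scheme), "positive")
})

test_that("isotropic FWE stage is exact in construction and initializes well", {
  set.seed(3)
  Dt <- axial_tensor(c(0, 1, 1), 1.5e-3, 0.5e-3)
  vox <- bitensor_voxel(80, 0.4, diag(3) * 3.0e-3, Dt)
  s <- simulate_signal(vox, hcpa_scheme)
  iso <- fit_isotropic_fwe(s, hcpa_scheme)
  expect_equal(tensor_metrics(iso$D_fluid)$FA, 0)          # exact by design
  expect_equal(unname(iso$D_fluid), unname(diag(3) * 3.0e-3))
  expect_lt(abs(iso$f - 0.4), 0.02)
})

test_that("anisotropic refinement never increases the RSS of its warm start", {
  set.seed(21)
  for (i in 1:5) {
    vox <- random_truth_voxel()
    s <- add_rician_noise(simulate_signal(vox, hcpa_scheme), sigma = 100 / 20,
                          seed = i)
    iso <- fit_isotropic_fwe(s, hcpa_scheme)
    fit <- fit_bitensor(s, hcpa_scheme)
    expect_lte(fit$rss, iso$rss + 1e-9 * iso$rss)
  }
})

test_that("fluid FA stays near zero when the truth is isotropic free water", {
  set.seed(5)
  fas <- replicate(20, {
    Dt <- axial_tensor(stats::rnorm(3), stats::runif(1, 1, 2) * 1e-3,
                       stats::runif(1, 0.3, 0.8) * 1e-3)
    vox <- bitensor_voxel(100, stats::runif(1, 0.2, 0.7),
                          diag(3) * 3.0e-3, Dt)
    fit <- fit_bitensor(simulate_signal(vox, hcpa_scheme), hcpa_scheme)
    tensor_metrics(fit$D_fluid)$FA
  })
  expect_lte(median(fas), 0.1)
})

test_that("fit object supports the standard modelling methods", {
  set.seed(9)
  vox <- random_truth_voxel()
  s <- simulate_signal(vox, hcpa_scheme)
  fit <- fit_bitensor(s, hcpa_scheme)
  cf <- coef(fit)
  expect_named(cf, c("S0", "f", "FWAD", "FWRD", "FWMD", "FWFA",
                     "tAD", "tRD", "tMD", "tFA"))
  expect_equal(fitted(fit) + residuals(fit), s, tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit))
  expect_output(print(fit), "Bi-tensor fit")
  # label convention: fluid is the faster compartment
  expect_gte(cf[["FWMD"]], cf[["tMD"]])
})
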