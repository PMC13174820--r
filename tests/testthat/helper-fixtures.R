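# Shared fixtures, built once per test run.

hcpa_scheme <- make_scheme("hcpa")
adni_scheme <- make_scheme("adni")

# two-volume scheme (one b0, one DWI along x) for hand-computable signals
tiny_scheme <- function(b = 1000, dir = c(1, 0, 0)) {
  acq_scheme(c(0, b), rbind(c(0, 0, 0), dir / sqrt(sum(dir^2))))
}

# random PSD tensor with eigenvalues in [lo, hi] (units mm^2/s)
random_psd_tensor <- function(lo = 0.3e-3, hi = 2.5e-3) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  ev <- stats::runif(3, lo, hi)
  q %*% (ev * t(q))
}

# random bi-tensor truth in the regime the fitter targets
random_truth_voxel <- function(f_range = c(0.1, 0.9), S0 = 100) {
  f <- stats::runif(1, f_range[1], f_range[2])
  Df <- axial_tensor(stats::rnorm(3), stats::runif(1, 3, 4.5) * 1e-3,
                     stats::runif(1, 2, 3) * 1e-3)
  Dt <- axial_tensor(stats::rnorm(3), stats::runif(1, 1, 2) * 1e-3,
                     stats::runif(1, 0.3, 0.8) * 1e-3)
  bitensor_voxel(S0, f, Df, Dt)
}

# independent eigenvalue oracle: closed-form roots of the characteristic
# polynomial of a symmetric 3x3 matrix (trigonometric method)
charpoly_eigenvalues <- function(A) {
  p1 <- A[1, 2]^2 + A[1, 3]^2 + A[2, 3]^2
  q <- sum(diag(A)) / 3
  p2 <- sum((diag(A) - q)^2) + 2 * p1
  p <- sqrt(p2 / 6)
  if (p < 1e-300) return(rep(q, 3))
  B <- (A - q * diag(3)) / p
  r <- det(B) / 2
  r <- min(max(r, -1), 1)
  phi <- acos(r) / 3
  ev <- q + 2 * p * cos(phi + c(0, -2, 2) * pi / 3)
  sort(ev, decreasing = TRUE)
}

# small WM slab phantom helpers
slab_masks <- function(nx = 6, ny = 6, nz = 12) {
  wm <- array(FALSE, c(nx, ny, nz)); wm[, , 2:(nz - 1)] <- TRUE
  gmb <- array(FALSE, c(nx, ny, nz)); gmb[, , 1] <- TRUE
  dpb <- array(FALSE, c(nx, ny, nz)); dpb[, , nz] <- TRUE
  list(wm = wm, gmb = gmb, dpb = dpb)
}
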