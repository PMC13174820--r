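# Symmetric 3x3 diffusion tensors are passed around either as full matrices
# or as length-6 vectors (dxx, dyy, dzz, dxy, dxz, dyz). Units: mm^2/s.

#' Pack a symmetric tensor into its six unique entries
#' @param D symmetric 3 x 3 matrix
#' @return numeric length 6: (dxx, dyy, dzz, dxy, dxz, dyz)
#' @export
dt_vec <- function(D) {
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Unpack six unique entries into a symmetric tensor
#' @param v numeric length 6 (dxx, dyy, dzz, dxy, dxz, dyz)
#' @return symmetric 3 x 3 matrix
#' @export
dt_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

# fast closed-form eigenvalues of a symmetric 3x3 matrix (trigonometric
# solution of the characteristic cubic), descending; used in hot loops
eig3_vals <- function(A) {
  p1 <- A[4]^2 + A[7]^2 + A[8]^2   # A[1,2]^2 + A[1,3]^2 + A[2,3]^2
  q <- (A[1] + A[5] + A[9]) / 3
  if (p1 == 0) return(sort(c(A[1], A[5], A[9]), decreasing = TRUE))
  p2 <- (A[1] - q)^2 + (A[5] - q)^2 + (A[9] - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  B <- (A - q * diag(3)) / p
  r <- (B[1] * (B[5] * B[9] - B[6] * B[8]) -
          B[4] * (B[2] * B[9] - B[6] * B[7]) +
          B[7] * (B[2] * B[8] - B[5] * B[7])) / 2
  r <- min(max(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  c(e1, 3 * q - e1 - e3, e3)
}

#' Check positive semi-definiteness of a diffusion tensor
#' @param D symmetric 3 x 3 matrix
#' @param tol eigenvalue tolerance (relative to largest)
#' @keywords internal
is_psd <- function(D, tol = 1e-8) {
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  ev[3] >= -tol * max(abs(ev[1]), 1e-12)
}

#' Scalar metrics of a diffusion tensor
#'
#' Eigenvalue-derived metrics: axial diffusivity AD = lambda1, radial
#' RD = (lambda2 + lambda3) / 2, mean MD, and fractional anisotropy
#' FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||. Applied to a fitted fluid
#' tensor these are the FWAD/FWRD/FWMD/FWFA measures; applied to the tissue
#' tensor, tAD/tRD/tMD/tFA.
#'
#' @param D symmetric positive semi-definite 3 x 3 tensor (mm^2/s), or a
#'   length-6 vector as in \code{\link{dt_vec}}.
#' @param tol tolerance for negative eigenvalues (relative); beyond it the
#'   tensor is rejected as degenerate.
#' @return list with \code{lambda} (sorted descending), \code{AD}, \code{RD},
#'   \code{MD}, \code{FA}.
#' @export
tensor_metrics <- function(D, tol = 1e-6) {
  if (is.numeric(D) && length(D) == 6L) D <- dt_mat(D)
  if (max(abs(D - t(D))) > 1e-12 * max(abs(D), 1e-300))
    stop("tensor is not symmetric", call. = FALSE)
  ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (ev[3] < -tol * max(abs(ev[1]), 1e-12))
    stop("degenerate tensor: negative eigenvalue beyond tolerance",
         call. = FALSE)
  ev <- pmax(ev, 0)
  md <- mean(ev)
  nrm <- sqrt(sum(ev^2))
  fa <- if (nrm == 0) 0 else sqrt(1.5) * sqrt(sum((ev - md)^2)) / nrm
  list(lambda = ev, AD = ev[1], RD = (ev[2] + ev[3]) / 2, MD = md,
       FA = min(max(fa, 0), 1))
}

#' Build a cylindrically symmetric tensor from axis and axial/radial values
#'
#' @param axis principal direction (3-vector, need not be unit).
#' @param ad axial diffusivity (mm^2/s).
#' @param rd radial diffusivity (mm^2/s).
#' @return symmetric 3 x 3 tensor with eigenvalues (ad, rd, rd).
#' @export
axial_tensor <- function(axis, ad, rd) {
  u <- axis / sqrt(sum(axis^2))
  rd * diag(3) + (ad - rd) * tcrossprod(u)
}
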