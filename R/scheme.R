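#' Multi-shell diffusion acquisition scheme
#'
#' Bundles b-values and gradient directions into a validated scheme object.
#' Directions for diffusion-weighted volumes (b > 0) must be unit vectors;
#' b0 volumes may carry a zero vector.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs numeric matrix of gradient directions, either n x 3 or 3 x n
#'   (FSL convention: three rows). Stored internally as n x 3.
#' @param require_multishell if TRUE (default FALSE), error unless at least
#'   two distinct nonzero shells are present (needed for bi-tensor fitting).
#'
#' @return an object of class \code{acq_scheme}: list with elements
#'   \code{bvals}, \code{bvecs} (n x 3), \code{b0} (logical index of b = 0
#'   volumes), \code{shells} (sorted distinct nonzero b-values).
#' @export
acq_scheme <- function(bvals, bvecs, require_multishell = FALSE) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must be an n x 3 (or 3 x n) matrix", call. = FALSE)
  if (nrow(bvecs) != length(bvals))
    stop("bvals and bvecs disagree in length", call. = FALSE)
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative", call. = FALSE)
  b0 <- bvals == 0
  if (!any(b0))
    stop("scheme must contain at least one b0 volume", call. = FALSE)
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- !b0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop(sum(bad), " diffusion-weighted direction(s) are not unit vectors",
         call. = FALSE)
  shells <- sort(unique(bvals[!b0]))
  if (require_multishell && length(shells) < 2L)
    stop("bi-tensor fitting requires at least two distinct nonzero shells",
         call. = FALSE)
  structure(
    list(bvals = bvals, bvecs = bvecs, b0 = b0, shells = shells),
    class = "acq_scheme"
  )
}

#' @export
print.acq_scheme <- function(x, ...) {
  cat("Acquisition scheme:", length(x$bvals), "volumes\n")
  cat("  b0 volumes:", sum(x$b0), "\n")
  for (s in x$shells)
    cat(sprintf("  b = %g s/mm^2: %d directions\n", s, sum(x$bvals == s)))
  invisible(x)
}

#' Number of volumes in a scheme
#' @param x an \code{acq_scheme}
#' @param ... ignored
#' @export
length.acq_scheme <- function(x) length(x$bvals)

#' Design matrix of b-weighted quadratic forms
#'
#' Row i is b_i * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz) so that
#' \code{B \%*\% dt_vec(D)} gives b * g' D g per volume.
#' @keywords internal
scheme_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3]) * b
}

#' Read FSL-style gradient tables
#'
#' @param bval_file path to a one-row whitespace-separated b-value file.
#' @param bvec_file path to a three-row (x, y, z) direction file.
#' @param ... passed to \code{\link{acq_scheme}}.
#' @return an \code{acq_scheme}.
#' @export
read_scheme <- function(bval_file, bvec_file, ...) {
  bvals <- scan(bval_file, quiet = TRUE)
  bvecs <- matrix(scan(bvec_file, quiet = TRUE), nrow = 3L, byrow = TRUE)
  acq_scheme(bvals, bvecs, ...)
}

#' Write FSL-style gradient tables
#'
#' @param scheme an \code{acq_scheme}.
#' @param bval_file,bvec_file output paths.
#' @export
write_scheme <- function(scheme, bval_file, bvec_file) {
  cat(paste(format(scheme$bvals, trim = TRUE), collapse = " "), "\n",
      file = bval_file, sep = "")
  v <- t(scheme$bvecs)
  con <- file(bvec_file, "w")
  for (i in 1:3)
    cat(paste(format(v[i, ], trim = TRUE, digits = 10), collapse = " "),
        "\n", file = con, sep = "")
  close(con)
  invisible(scheme)
}

#' Quasi-uniform unit directions by electrostatic repulsion
#'
#' Seeded random start followed by a fixed number of repulsion steps on the
#' sphere; deterministic given the seed.
#' @keywords internal
repulsion_directions <- function(n, seed = 1L, n_iter = 200L) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  step <- 0.05
  for (it in seq_len(n_iter)) {
    frc <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d <- v - matrix(v[i, ], n, 3, byrow = TRUE)
      # antipodal symmetry: repel from both g_j and -g_j
      d2 <- rowSums(d^2); d2[i] <- Inf
      da <- v + matrix(v[i, ], n, 3, byrow = TRUE)
      da2 <- rowSums(da^2); da2[i] <- Inf
      frc[i, ] <- -colSums(d / (d2^1.5 + 1e-12)) - colSums(da / (da2^1.5 + 1e-12))
    }
    v <- v - step * frc / n
    v <- v / sqrt(rowSums(v^2))
  }
  v
}

#' Preset acquisition schemes
#'
#' \code{"hcpa"}: 6 b0, 45 directions at b = 1500 and 45 at b = 3000 s/mm^2
#' (96 volumes). \code{"adni"}: 14 b0, 6 directions at b = 500, 56 at
#' b = 1000 and 56 at b = 2000 s/mm^2 (132 volumes). Directions are
#' quasi-uniform on the sphere (seeded electrostatic repulsion).
#'
#' @param preset one of \code{"hcpa"}, \code{"adni"}.
#' @param seed integer seed for the direction sets.
#' @return an \code{acq_scheme}.
#' @export
make_scheme <- function(preset = c("hcpa", "adni"), seed = 20260101L) {
  preset <- match.arg(preset)
  layout <- switch(preset,
    hcpa = list(n_b0 = 6L,  shells = c(1500, 3000), ndir = c(45L, 45L)),
    adni = list(n_b0 = 14L, shells = c(500, 1000, 2000), ndir = c(6L, 56L, 56L))
  )
  bvals <- rep(0, layout$n_b0)
  bvecs <- matrix(0, layout$n_b0, 3)
  for (i in seq_along(layout$shells)) {
    dirs <- repulsion_directions(layout$ndir[i], seed = seed + i)
    bvals <- c(bvals, rep(layout$shells[i], layout$ndir[i]))
    bvecs <- rbind(bvecs, dirs)
  }
  acq_scheme(bvals, bvecs)
}
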