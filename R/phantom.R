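# Digital DWI phantoms: white-matter slab with embedded perivascular-space
# tubes and WMH blobs, rendered through the bi-tensor forward model.

#' Phantom specification
#'
#' Describes a slab phantom: WM occupying the interior of the grid in z
#' (with gray-matter boundary at the low-z face and a deep boundary at the
#' high-z face), tubular pAs structures running along z, and spherical WMH
#' blobs. Each tissue class carries a full bi-tensor truth. Defaults place
#' high anisotropic free-water content in the tubes (FWVF 0.9, fluid AD
#' along the tube axis) against low-free-water WM (FWVF 0.1), the ordering
#' expected between pAs and parenchyma.
#'
#' @param dims grid dimensions (default c(12, 12, 10)).
#' @param spacing voxel spacing mm (default 1.5 isotropic).
#' @param n_tubes number of pAs tubes (default 2).
#' @param tube_radius_mm tube radius (default 1.6 mm).
#' @param n_wmh number of WMH blobs (default 1).
#' @param wmh_radius_mm blob radius (default 2.2 mm).
#' @param S0 b0 signal level (default 100).
#' @param recipes named list of \code{\link{bitensor_voxel}} truths for
#'   \code{wm}, \code{pas}, \code{wmh}.
#' @param seed integer seed controlling noise (placement is deterministic).
#' @return list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(dims = c(12L, 12L, 10L), spacing = rep(1.5, 3),
                         n_tubes = 2L, tube_radius_mm = 1.6,
                         n_wmh = 1L, wmh_radius_mm = 2.2, S0 = 100,
                         recipes = NULL, seed = 1L) {
  if (is.null(recipes))
    recipes <- list(
      wm = bitensor_voxel(S0, 0.1,
                          D_fluid = diag(3) * 3.0e-3,
                          D_tissue = axial_tensor(c(0, 1, 0), 1.5e-3,
                                                  0.4e-3)),
      pas = bitensor_voxel(S0, 0.9,
                           D_fluid = axial_tensor(c(0, 0, 1), 4.0e-3,
                                                  2.2e-3),
                           D_tissue = axial_tensor(c(0, 0, 1), 1.5e-3,
                                                   0.4e-3)),
      wmh = bitensor_voxel(S0, 0.4,
                           D_fluid = diag(3) * 3.0e-3,
                           D_tissue = diag(3) * 1.0e-3))
  structure(list(dims = as.integer(dims), spacing = spacing,
                 n_tubes = as.integer(n_tubes),
                 tube_radius_mm = tube_radius_mm,
                 n_wmh = as.integer(n_wmh),
                 wmh_radius_mm = wmh_radius_mm, S0 = S0,
                 recipes = recipes, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Render a phantom to DWI, truth maps and masks
#'
#' Voxel labels: 1 = WM, 2 = pAs tube, 3 = WMH. z = 1 is the gray-matter
#' boundary layer, z = nz the deep boundary. Signals come from
#' \code{\link{simulate_signal}} on each label's truth; Rician noise of
#' standard deviation \code{S0 / snr} is added when \code{snr} is finite.
#' Tube and blob placement is deterministic; an overlap between a WMH blob
#' and a tube is an error (labels must partition the volume).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param scheme an \code{\link{acq_scheme}}.
#' @param snr b0 signal-to-noise ratio (Inf = noiseless, default).
#' @return list: \code{dwi} (4-D array), \code{labels}, \code{truth}
#'   (FWVF/FWAD truth arrays), \code{masks} (wm, pas, wmh, gm_boundary,
#'   deep_boundary, atlas with two cortical labels), \code{spec},
#'   \code{scheme}.
#' @export
render_phantom <- function(spec, scheme, snr = Inf) {
  dims <- spec$dims
  sp <- spec$spacing
  lab <- array(0L, dims)
  zint <- 2:(dims[3] - 1)             # WM interior in z
  lab[, , zint] <- 1L

  # pAs tubes along z, spread over x and over the two atlas halves in y
  ctr_y <- (dims[2] + 1) / 2
  xs <- round(seq(dims[1] / 3, 2 * dims[1] / 3,
                  length.out = max(spec$n_tubes, 1)))
  ys <- round(seq(dims[2] / 3, 2 * dims[2] / 3,
                  length.out = max(spec$n_tubes, 1)))
  co <- arrayInd(seq_len(prod(dims)), dims)
  for (t in seq_len(spec$n_tubes)) {
    d2 <- ((co[, 1] - xs[t]) * sp[1])^2 + ((co[, 2] - ys[t]) * sp[2])^2
    sel <- d2 <= spec$tube_radius_mm^2 & co[, 3] %in% zint
    lab[sel] <- 2L
  }
  # WMH blobs in a corner of the slab
  if (spec$n_wmh > 0) {
    bx <- round(dims[1] * 0.8); by <- round(dims[2] * 0.25)
    bz <- round(mean(zint))
    for (wbl in seq_len(spec$n_wmh)) {
      d2 <- ((co[, 1] - bx) * sp[1])^2 + ((co[, 2] - by - 3 * (wbl - 1)) *
                                            sp[2])^2 +
        ((co[, 3] - bz) * sp[3])^2
      sel <- d2 <= spec$wmh_radius_mm^2 & co[, 3] %in% zint
      if (any(lab[sel] == 2L))
        stop("overlapping labels: WMH blob intersects a pAs tube",
             call. = FALSE)
      lab[sel] <- 3L
    }
  }

  truth_fwvf <- array(NA_real_, dims)
  truth_fwad <- array(NA_real_, dims)
  nvol <- length(scheme$bvals)
  dwi <- array(0, c(dims, nvol))
  flat <- matrix(0, prod(dims), nvol)
  for (li in 1:3) {
    nm <- c("wm", "pas", "wmh")[li]
    vx <- which(lab == li)
    if (!length(vx)) next
    sig <- simulate_signal(spec$recipes[[nm]], scheme)
    flat[vx, ] <- matrix(sig, length(vx), nvol, byrow = TRUE)
    truth_fwvf[vx] <- spec$recipes[[nm]]$f
    truth_fwad[vx] <- tensor_metrics(spec$recipes[[nm]]$D_fluid)$AD
  }
  if (is.finite(snr))
    flat <- add_rician_noise(flat, sigma = spec$S0 / snr, seed = spec$seed)
  dwi <- array(flat, c(dims, nvol))

  gmb <- array(FALSE, dims); gmb[, , 1] <- TRUE
  dpb <- array(FALSE, dims); dpb[, , dims[3]] <- TRUE
  atlas <- array(0L, dims)
  atlas[, , 1] <- ifelse(co[co[, 3] == 1, 2] <= ctr_y, 1L, 2L)
  masks <- list(wm = lab == 1L, pas = lab == 2L, wmh = lab == 3L,
                gm_boundary = gmb, deep_boundary = dpb, atlas = atlas)
  list(dwi = dwi, labels = lab, truth = list(FWVF = truth_fwvf,
                                             FWAD = truth_fwad),
       masks = masks, spec = spec, scheme = scheme)
}

#' Add Rician noise to magnitude signals
#'
#' M = |S + n1 + i n2| with independent zero-mean Gaussian n1, n2 of
#' standard deviation \code{sigma}; seeded and reproducible. With
#' \code{sigma = 0} the input is returned unchanged.
#'
#' @param signal numeric vector/matrix/array of noise-free magnitudes.
#' @param sigma Gaussian channel noise SD (>= 0).
#' @param seed integer seed.
#' @return noisy magnitudes, same shape.
#' @export
add_rician_noise <- function(signal, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(signal)
  set.seed(seed)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}
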