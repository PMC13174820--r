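# Voxelwise application of the bi-tensor fit over a masked 4-D volume.

#' Construct a scalar map set
#' @keywords internal
scalar_maps <- function(maps, spacing, provenance, n_degenerate = 0L) {
  structure(list(maps = maps, spacing = spacing, provenance = provenance,
                 n_degenerate = n_degenerate),
            class = "scalar_maps")
}

#' @export
print.scalar_maps <- function(x, ...) {
  dm <- if (length(x$maps)) dim(x$maps[[1]]) else NULL
  cat("Scalar map set:", paste(names(x$maps), collapse = ", "), "\n")
  if (!is.null(dm))
    cat("  grid ", paste(dm, collapse = " x "), ", spacing ",
        paste(x$spacing, collapse = " x "), " mm\n", sep = "")
  cat("  fitted voxels:", sum(x$provenance > 0L),
      "(fallback:", sum(x$provenance == 2L), ")",
      "degenerate excluded:", x$n_degenerate, "\n")
  invisible(x)
}

map_names <- c("FWVF", "FWAD", "FWRD", "FWMD", "FWFA",
               "tAD", "tRD", "tMD", "tFA", "S0", "fit_rss",
               "tDxx", "tDyy", "tDzz")

#' Fit the bi-tensor model over a masked volume
#'
#' Applies \code{\link{fit_bitensor}} to every voxel of the mask and collects
#' the derived scalar maps (FWVF, fluid and tissue tensor metrics, S0,
#' residual sum of squares, and the diagonal tissue-tensor elements). Two
#' volume-level refinements (both on by default, see
#' \code{\link{fit_config}}) improve noisy data: the Rician noise floor is
#' removed from the magnitudes using the noise SD pooled over the repeated
#' b0 volumes, and a second voxelwise pass softly anchors each voxel's
#' compartment mean diffusivities to its 26-neighborhood medians, which
#' resolves the free-water/tissue-diffusivity trade-off of per-voxel
#' two-compartment fits. Voxels with non-positive or non-finite signal, or
#' with near-zero b0, are dropped from the mask and counted. Values outside
#' the (effective) mask are NA.
#'
#' @param dwi 4-D numeric array (x, y, z, volume).
#' @param mask 3-D logical/0-1 array on the same grid.
#' @param scheme an \code{\link{acq_scheme}}.
#' @param config a \code{\link{fit_config}}.
#' @param spacing voxel spacing in mm (length 3).
#' @return object of class \code{scalar_maps}; \code{$provenance} is 0
#'   outside the mask, 1 for converged anisotropic fits, 2 for fallback to
#'   the isotropic initialization.
#' @export
fit_volume <- function(dwi, mask, scheme, config = fit_config(),
                       spacing = c(1, 1, 1)) {
  dwi <- as.array(dwi)
  if (length(dim(dwi)) != 4L)
    stop("dwi must be a 4-D array", call. = FALSE)
  dims <- dim(dwi)[1:3]
  mask <- array(as.logical(mask), dim = dim(as.array(mask)))
  if (!identical(dim(mask), dims))
    stop("mask and dwi grids disagree", call. = FALSE)
  if (dim(dwi)[4] != length(scheme$bvals))
    stop("dwi volume count does not match the scheme", call. = FALSE)

  empty <- array(NA_real_, dims)
  maps <- stats::setNames(rep(list(empty), length(map_names)), map_names)
  prov <- array(0L, dims)
  idx <- which(mask)
  if (!length(idx)) {
    warning("empty mask: no voxels fitted")
    return(scalar_maps(maps, spacing, prov))
  }
  nvol <- dim(dwi)[4]
  flat <- matrix(dwi, prod(dims), nvol)
  sig <- flat[idx, , drop = FALSE]
  b0m <- rowMeans(sig[, scheme$b0, drop = FALSE])
  good <- apply(sig, 1, function(s) all(is.finite(s)) && all(s > 0)) &
    b0m > 1e-10
  n_deg <- sum(!good)
  if (n_deg) message(n_deg, " degenerate voxel(s) excluded from the mask")

  if (config$rician_correct && sum(scheme$b0) >= 3L && any(good)) {
    sigma <- stats::median(apply(sig[good, scheme$b0, drop = FALSE], 1,
                                 stats::sd))
    if (is.finite(sigma) && sigma > 0)
      sig <- sqrt(pmax(sig^2 - 2 * sigma^2, (0.3 * sigma)^2))
  }

  # when the spatial pass follows, it rescues the occasional local minimum,
  # so the first pass can skip the deterministic restart
  cfg1 <- config
  if (config$spatial_refine) cfg1$extra_f_starts <- numeric(0)
  fits <- vector("list", length(idx))
  for (j in which(good)) fits[[j]] <- fit_bitensor(sig[j, ], scheme, cfg1)

  if (config$spatial_refine && sum(good) > 1L) {
    row_of <- array(0L, dims)
    row_of[idx] <- seq_along(idx)
    off <- conn_offsets(26L)
    tmd <- vapply(fits, function(f)
      if (is.null(f)) NA_real_ else tensor_metrics(f$D_tissue)$MD, 0)
    fmd <- vapply(fits, function(f)
      if (is.null(f)) NA_real_ else tensor_metrics(f$D_fluid)$MD, 0)
    co <- arrayInd(idx, dims)
    for (j in which(good)) {
      nb <- sweep(off, 2, co[j, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      r <- row_of[nb[ok, , drop = FALSE]]
      r <- r[r > 0]
      r <- r[!is.na(tmd[r])]
      if (length(r) < 3L) next
      ft <- fits[[j]]
      prep <- fit_prepare(sig[j, ], scheme)
      res <- aniso_stage(prep, config, ft$f, ft$D_tissue * DSCALE,
                         ft$D_fluid * DSCALE,
                         anchors = list(tmd = stats::median(tmd[r]) * DSCALE,
                                        fmd = stats::median(fmd[r]) * DSCALE,
                                        w = config$spatial_weight))
      fits[[j]] <- finish_fit(prep, scheme, res$f, res$Dt / DSCALE,
                              res$Df / DSCALE, res$rss, res$converged,
                              res$niter, "anisotropic_refined")
    }
  }

  for (j in which(good)) {
    ft <- fits[[j]]
    v <- idx[j]
    cf <- coef(ft)
    maps$FWVF[v] <- cf[["f"]];   maps$FWAD[v] <- cf[["FWAD"]]
    maps$FWRD[v] <- cf[["FWRD"]]; maps$FWMD[v] <- cf[["FWMD"]]
    maps$FWFA[v] <- cf[["FWFA"]]; maps$tAD[v] <- cf[["tAD"]]
    maps$tRD[v] <- cf[["tRD"]];  maps$tMD[v] <- cf[["tMD"]]
    maps$tFA[v] <- cf[["tFA"]];  maps$S0[v] <- cf[["S0"]]
    maps$fit_rss[v] <- ft$rss
    maps$tDxx[v] <- ft$D_tissue[1, 1]
    maps$tDyy[v] <- ft$D_tissue[2, 2]
    maps$tDzz[v] <- ft$D_tissue[3, 3]
    prov[v] <- if (ft$method == "fallback_isotropic") 2L else 1L
  }
  scalar_maps(maps, spacing, prov, n_deg)
}

#' Conventional single-tensor DTI fit over a masked volume
#'
#' Log-linear least-squares tensor fit of the whole signal (no free-water
#' separation); returns the diagonal diffusivity maps used by the DTI-ALPS
#' index along with MD/FA.
#'
#' @inheritParams fit_volume
#' @return list of 3-D arrays: \code{Dxx}, \code{Dyy}, \code{Dzz},
#'   \code{MD}, \code{FA} (NA outside the mask).
#' @export
fit_dti_volume <- function(dwi, mask, scheme) {
  dwi <- as.array(dwi)
  dims <- dim(dwi)[1:3]
  mask <- array(as.logical(mask), dim = dim(as.array(mask)))
  if (!identical(dim(mask), dims))
    stop("mask and dwi grids disagree", call. = FALSE)
  B <- scheme_design(scheme)[!scheme$b0, , drop = FALSE] / DSCALE
  qrB <- qr(B)
  out <- stats::setNames(rep(list(array(NA_real_, dims)), 5),
                         c("Dxx", "Dyy", "Dzz", "MD", "FA"))
  flat <- matrix(dwi, prod(dims), dim(dwi)[4])
  for (v in which(mask)) {
    s <- flat[v, ]
    S0 <- mean(s[scheme$b0])
    if (!is.finite(S0) || S0 <= 0 || any(s <= 0)) next
    dvec <- qr.coef(qrB, -log(pmax(s[!scheme$b0] / S0, 1e-6))) / DSCALE
    out$Dxx[v] <- dvec[1]; out$Dyy[v] <- dvec[2]; out$Dzz[v] <- dvec[3]
    tm <- try(tensor_metrics(dt_mat(dvec), tol = Inf), silent = TRUE)
    if (!inherits(tm, "try-error")) {
      out$MD[v] <- tm$MD; out$FA[v] <- tm$FA
    }
  }
  out
}
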