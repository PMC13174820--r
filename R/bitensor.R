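# Bi-tensor (tissue + free-water) diffusion model.
#
# S(b, g) = S0 * [ f * exp(-b g' D_fluid g) + (1 - f) * exp(-b g' D_tissue g) ]
#
# Unlike isotropic free-water elimination, the fluid compartment carries a
# full anisotropic tensor, so directional diffusivity of perivascular fluid
# (FWAD etc.) is estimable. Internally diffusivities are scaled by 1e3
# (units of 1e-3 mm^2/s) so b * D is O(1) for typical in vivo values.

DSCALE <- 1e3

#' Construct a bi-tensor voxel state
#'
#' @param S0 non-diffusion-weighted signal (> 0, arbitrary units).
#' @param f free-water volume fraction in [0, 1] (the FWVF).
#' @param D_fluid,D_tissue symmetric PSD 3 x 3 tensors (mm^2/s). By
#'   convention the fluid tensor has the larger mean diffusivity.
#' @return object of class \code{bitensor_voxel}.
#' @export
bitensor_voxel <- function(S0, f, D_fluid, D_tissue) {
  if (!is.finite(S0) || S0 <= 0)
    stop("invalid model: S0 must be positive", call. = FALSE)
  if (!is.finite(f) || f < 0 || f > 1)
    stop("invalid model: f must lie in [0, 1]", call. = FALSE)
  for (D in list(D_fluid, D_tissue))
    if (!is_psd(D, tol = 1e-6))
      stop("invalid model: tensor is not positive semi-definite",
           call. = FALSE)
  structure(list(S0 = S0, f = f,
                 D_fluid = (D_fluid + t(D_fluid)) / 2,
                 D_tissue = (D_tissue + t(D_tissue)) / 2),
            class = "bitensor_voxel")
}

#' Forward-simulate the bi-tensor diffusion signal
#'
#' @param voxel a \code{bitensor_voxel} (or \code{bitensor_fit}).
#' @param scheme an \code{\link{acq_scheme}}.
#' @return numeric signal vector, one value per volume; equals \code{S0}
#'   exactly at b = 0 and is positive and at most \code{S0} elsewhere.
#' @export
simulate_signal <- function(voxel, scheme) {
  # re-validate invariants whether or not the input is already classed
  voxel <- bitensor_voxel(voxel$S0, voxel$f, voxel$D_fluid, voxel$D_tissue)
  B <- scheme_design(scheme)
  qf <- drop(B %*% dt_vec(voxel$D_fluid))
  qt <- drop(B %*% dt_vec(voxel$D_tissue))
  voxel$S0 * (voxel$f * exp(-qf) + (1 - voxel$f) * exp(-qt))
}

#' Fitting configuration for the bi-tensor model
#'
#' @param d_free isotropic free-water diffusivity (mm^2/s) used by the
#'   isotropic stage and as the fluid-tensor initialization; default body
#'   temperature value 3.0e-3.
#' @param tissue_bounds,fluid_bounds allowed eigenvalue ranges (mm^2/s),
#'   enforced by penalty.
#' @param md_prior_weight relative weight of the soft prior pulling fluid MD
#'   toward \code{d_free} (small by default so FWMD can vary with the data).
#' @param bound_weight penalty weight per unit (1e-3 mm^2/s) of eigenvalue
#'   bound violation.
#' @param maxit maximum Levenberg-Marquardt iterations.
#' @param ftol,ptol,gtol LM convergence tolerances (relative reduction,
#'   parameter step, gradient norm).
#' @param f_grid free-water fractions scanned by the isotropic initializer.
#' @param extra_f_starts additional deterministic anisotropic starts at these
#'   free-water fractions (guards against local minima; empty to disable).
#' @param rician_correct volume fitting only: estimate the noise SD from the
#'   repeated b0 volumes and remove the Rician noise floor from the
#'   magnitudes (method of moments, E[M^2] = S^2 + 2 sigma^2) before
#'   fitting. A no-op on noiseless data.
#' @param spatial_refine volume fitting only: second voxelwise pass that
#'   softly anchors each voxel's tissue and fluid mean diffusivities to the
#'   26-neighborhood medians of the first pass, resolving the
#'   f/tissue-diffusivity degeneracy of the two-compartment model.
#' @param spatial_weight penalty weight of the spatial anchors (per
#'   1e-3 mm^2/s deviation).
#' @return list of class \code{bitensor_config}.
#' @export
fit_config <- function(d_free = 3.0e-3,
                       tissue_bounds = c(0.05e-3, 2.5e-3),
                       fluid_bounds = c(2.0e-3, 6.0e-3),
                       md_prior_weight = 1e-3,
                       bound_weight = 1,
                       maxit = 500L,
                       ftol = 1e-6, ptol = 1e-6, gtol = 1e-8,
                       f_grid = seq(0.02, 0.98, by = 0.04),
                       extra_f_starts = 0.8,
                       rician_correct = TRUE,
                       spatial_refine = TRUE,
                       spatial_weight = 2) {
  structure(list(d_free = d_free, tissue_bounds = tissue_bounds,
                 fluid_bounds = fluid_bounds,
                 md_prior_weight = md_prior_weight,
                 bound_weight = bound_weight, maxit = as.integer(maxit),
                 ftol = ftol, ptol = ptol, gtol = gtol, f_grid = f_grid,
                 extra_f_starts = extra_f_starts,
                 rician_correct = rician_correct,
                 spatial_refine = spatial_refine,
                 spatial_weight = spatial_weight),
            class = "bitensor_config")
}

# --- internal parameterization helpers (scaled units) ---------------------

# lower-triangular Cholesky factor from 6 free parameters
chol_from_par <- function(p) {
  matrix(c(p[1], p[2], p[3],
           0,    p[4], p[5],
           0,    0,    p[6]), 3, 3)  # columns: L is lower triangular
}

par_from_spd <- function(D) {
  # Cholesky of a (possibly near-singular) SPD matrix, jittered if needed
  Dj <- D + diag(3) * max(1e-8, -min(eigen(D, symmetric = TRUE,
                                           only.values = TRUE)$values) * 2)
  L <- t(chol(Dj))
  c(L[1, 1], L[2, 1], L[3, 1], L[2, 2], L[3, 2], L[3, 3])
}

spd_from_par <- function(p) {
  L <- chol_from_par(p)
  tcrossprod(L)
}

# Jacobian of dvec(L L') with respect to the 6 Cholesky parameters
# (rows: dxx, dyy, dzz, dxy, dxz, dyz; columns: p1..p6)
jd_lower <- function(p) {
  matrix(c(2 * p[1], 0, 0, p[2], p[3], 0,
           0, 2 * p[2], 0, p[1], 0, p[3],
           0, 0, 2 * p[3], 0, p[1], p[2],
           0, 2 * p[4], 0, 0, 0, p[5],
           0, 0, 2 * p[5], 0, 0, p[4],
           0, 0, 2 * p[6], 0, 0, 0), 6, 6)
}

# rows of the penalty-block Jacobian for one tensor: d(penalties)/d(p);
# eigenvalue derivative dlambda_k/dD = v_k v_k'
penalty_jac_tensor <- function(D, p, lo, hi, w) {
  e <- eigen(D, symmetric = TRUE)
  JD <- jd_lower(p)
  dl <- matrix(0, 3, 6)             # dlambda_k / dp_j
  for (j in 1:6) {
    dD <- dt_mat(JD[, j])
    dl[, j] <- vapply(1:3, function(k)
      drop(crossprod(e$vectors[, k], dD %*% e$vectors[, k])), 0)
  }
  rbind(ifelse(e$values < lo, -w, 0) * dl,
        ifelse(e$values > hi, w, 0) * dl)
}

# penalty residuals for eigenvalue bounds (scaled units) and fluid MD prior
penalty_resid <- function(Dt, Df, config) {
  evt <- eig3_vals(Dt)
  evf <- eig3_vals(Df)
  tb <- config$tissue_bounds * DSCALE
  fb <- config$fluid_bounds * DSCALE
  w <- config$bound_weight
  c(w * pmax(0, tb[1] - evt), w * pmax(0, evt - tb[2]),
    w * pmax(0, fb[1] - evf), w * pmax(0, evf - fb[2]),
    config$md_prior_weight * ((evf[1] + evf[2] + evf[3]) / 3 -
                                config$d_free * DSCALE) /
      (config$d_free * DSCALE))
}

# log-linear single-tensor fit of normalized signal y at design B (scaled)
loglinear_tensor <- function(B, y) {
  ly <- log(pmax(y, 1e-6))
  qr.coef(qr(B), -ly)
}

# clamp a tensor's eigenvalues into [lo, hi] (scaled units)
clamp_eigs <- function(D, lo, hi) {
  e <- eigen(D, symmetric = TRUE)
  v <- pmin(pmax(e$values, lo), hi)
  e$vectors %*% (v * t(e$vectors))
}

#' Isotropic free-water-elimination fit
#'
#' Two-compartment fit with the fluid tensor constrained to
#' \code{d_free * I} (conventional FWE-DTI). Estimates the free-water
#' fraction and a full tissue tensor; used both as a baseline model and as
#' the warm start for the anisotropic fit.
#'
#' @param signal positive signal vector, one value per scheme volume.
#' @param scheme an \code{\link{acq_scheme}} with >= 2 nonzero shells.
#' @param config a \code{\link{fit_config}}.
#' @return a \code{bitensor_fit} whose fluid tensor is exactly
#'   \code{d_free * I} (fluid FA = 0 by construction).
#' @export
fit_isotropic_fwe <- function(signal, scheme, config = fit_config()) {
  prep <- fit_prepare(signal, scheme)
  ans <- iso_stage(prep, config)
  finish_fit(prep, scheme, f = ans$f,
             Dt = ans$Dt / DSCALE,
             Df = diag(3) * config$d_free,
             rss = ans$rss, converged = ans$converged, niter = ans$niter,
             method = "isotropic_fwe")
}

fit_prepare <- function(signal, scheme) {
  stopifnot(inherits(scheme, "acq_scheme"))
  if (length(scheme$shells) < 2L)
    stop("insufficient data: bi-tensor fitting requires at least two ",
         "distinct nonzero shells", call. = FALSE)
  signal <- as.numeric(signal)
  if (length(signal) != length(scheme$bvals))
    stop("signal length does not match the scheme", call. = FALSE)
  if (any(!is.finite(signal)) || any(signal <= 0))
    stop("insufficient data: signal must be positive and finite",
         call. = FALSE)
  S0 <- mean(signal[scheme$b0])
  dwi <- !scheme$b0
  B <- scheme_design(scheme)[dwi, , drop = FALSE] / DSCALE  # b in ms/um^2
  list(signal = signal, S0 = S0, y = signal[dwi] / S0, B = B, dwi = dwi)
}

iso_stage <- function(prep, config) {
  y <- prep$y; B <- prep$B
  b <- rowSums(B[, 1:3, drop = FALSE])      # scaled b per volume
  efree <- exp(-b * config$d_free * DSCALE)
  tb <- config$tissue_bounds * DSCALE
  best <- NULL
  for (f0 in config$f_grid) {
    yt <- pmax((y - f0 * efree) / (1 - f0), 1e-6)
    dvec <- loglinear_tensor(B, yt)
    Dt <- clamp_eigs(dt_mat(dvec), tb[1], tb[2])
    r <- f0 * efree + (1 - f0) * exp(-drop(B %*% dt_vec(Dt))) - y
    rss <- sum(r^2)
    if (is.null(best) || rss < best$rss)
      best <- list(f = f0, Dt = Dt, rss = rss)
  }
  # LM refinement over (logit f, tissue Cholesky), analytic Jacobian
  theta0 <- c(stats::qlogis(min(max(best$f, 0.02), 0.98)),
              par_from_spd(best$Dt))
  rfun <- function(th) {
    f <- stats::plogis(th[1])
    Dt <- spd_from_par(th[2:7])
    r <- f * efree + (1 - f) * exp(-drop(B %*% dt_vec(Dt))) - y
    evt <- eig3_vals(Dt)
    viol <- c(tb[1] - evt, evt - tb[2])
    viol[viol < 0] <- 0
    c(r, config$bound_weight * viol)
  }
  jfun <- function(th) {
    f <- stats::plogis(th[1])
    p <- th[2:7]
    Dt <- spd_from_par(p)
    et <- exp(-drop(B %*% dt_vec(Dt)))
    dQ <- B %*% jd_lower(p)
    J <- cbind((efree - et) * f * (1 - f), -(1 - f) * et * dQ)
    Jp <- cbind(0, config$bound_weight *
                  penalty_jac_tensor(Dt, p, tb[1], tb[2], 1))
    rbind(J, Jp)
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = theta0, fn = rfun, jac = jfun,
    control = minpack.lm::nls.lm.control(
      maxiter = config$maxit, ftol = config$ftol, ptol = config$ptol,
      gtol = config$gtol)))
  f <- stats::plogis(fit$par[1])
  Dt <- spd_from_par(fit$par[2:7])
  r <- f * efree + (1 - f) * exp(-drop(B %*% dt_vec(Dt))) - y
  rss <- sum(r^2)
  if (rss > best$rss) {            # keep the grid solution if LM wandered
    f <- best$f; Dt <- best$Dt; rss <- best$rss
  }
  list(f = f, Dt = Dt, rss = rss, converged = fit$info %in% 1:4,
       niter = fit$niter)
}

aniso_stage <- function(prep, config, f0, Dt0, Df0, anchors = NULL) {
  # anchors: optional list(tmd, fmd, w) pulling the tissue/fluid mean
  # diffusivities (scaled units) toward neighborhood values (spatial pass)
  y <- prep$y; B <- prep$B
  aw <- if (is.null(anchors)) 0 else anchors$w
  theta0 <- c(stats::qlogis(min(max(f0, 0.02), 0.98)),
              par_from_spd(Dt0), par_from_spd(Df0))
  rfun <- function(th) {
    f <- stats::plogis(th[1])
    Dt <- spd_from_par(th[2:7])
    Df <- spd_from_par(th[8:13])
    r <- f * exp(-drop(B %*% dt_vec(Df))) +
      (1 - f) * exp(-drop(B %*% dt_vec(Dt))) - y
    out <- c(r, penalty_resid(Dt, Df, config))
    if (aw > 0)
      out <- c(out,
               aw * ((Dt[1, 1] + Dt[2, 2] + Dt[3, 3]) / 3 - anchors$tmd),
               aw * ((Df[1, 1] + Df[2, 2] + Df[3, 3]) / 3 - anchors$fmd))
    out
  }
  jfun <- function(th) {
    f <- stats::plogis(th[1])
    pt <- th[2:7]; pf <- th[8:13]
    Dt <- spd_from_par(pt); Df <- spd_from_par(pf)
    et <- exp(-drop(B %*% dt_vec(Dt)))
    ef <- exp(-drop(B %*% dt_vec(Df)))
    J <- cbind((ef - et) * f * (1 - f),
               -(1 - f) * et * (B %*% jd_lower(pt)),
               -f * ef * (B %*% jd_lower(pf)))
    tb <- config$tissue_bounds * DSCALE
    fb <- config$fluid_bounds * DSCALE
    w <- config$bound_weight
    Jt <- penalty_jac_tensor(Dt, pt, tb[1], tb[2], w)
    Jf <- penalty_jac_tensor(Df, pf, fb[1], fb[2], w)
    zero6 <- matrix(0, 6, 6)
    # fluid-MD prior row: d(trace/3)/dp on the fluid block only
    md_row <- c(0, rep(0, 6),
                config$md_prior_weight / (3 * config$d_free * DSCALE) *
                  colSums(jd_lower(pf)[1:3, , drop = FALSE]))
    Jout <- rbind(J,
                  cbind(0, Jt, zero6),
                  cbind(0, zero6, Jf),
                  md_row)
    if (aw > 0)
      Jout <- rbind(Jout,
                    c(0, aw / 3 * colSums(jd_lower(pt)[1:3, , drop = FALSE]),
                      rep(0, 6)),
                    c(0, rep(0, 6),
                      aw / 3 * colSums(jd_lower(pf)[1:3, , drop = FALSE])))
    Jout
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = theta0, fn = rfun, jac = jfun,
    control = minpack.lm::nls.lm.control(
      maxiter = config$maxit, ftol = config$ftol, ptol = config$ptol,
      gtol = config$gtol)))
  f <- stats::plogis(fit$par[1])
  Dt <- spd_from_par(fit$par[2:7])
  Df <- spd_from_par(fit$par[8:13])
  r <- f * exp(-drop(B %*% dt_vec(Df))) +
    (1 - f) * exp(-drop(B %*% dt_vec(Dt))) - y
  list(f = f, Dt = Dt, Df = Df, rss = sum(r^2),
       converged = fit$info %in% 1:4, niter = fit$niter)
}

finish_fit <- function(prep, scheme, f, Dt, Df, rss, converged, niter,
                       method) {
  # label-switching convention: fluid is the faster compartment
  if (tensor_metrics(Df)$MD < tensor_metrics(Dt)$MD) {
    tmp <- Df; Df <- Dt; Dt <- tmp
    f <- 1 - f
  }
  structure(list(S0 = prep$S0, f = f, D_fluid = Df, D_tissue = Dt,
                 rss = rss * prep$S0^2, converged = converged,
                 niter = niter, method = method, scheme = scheme,
                 signal = prep$signal),
            class = c("bitensor_fit", "bitensor_voxel"))
}

#' Fit the anisotropic bi-tensor model to one voxel
#'
#' Staged estimation: (1) log-linear single-tensor fit, (2) isotropic
#' free-water-elimination fit over a deterministic grid of free-water
#' fractions with Levenberg-Marquardt refinement, (3) anisotropic fit with
#' both tensors parameterized by their Cholesky factors (guaranteeing
#' positive semi-definiteness) and the fraction by a logistic transform.
#' \code{S0} is fixed at the mean b0 signal. Physical eigenvalue bounds and
#' a weak prior pulling fluid MD toward \code{d_free} are enforced as
#' penalty residuals. If the anisotropic stage fails to improve on its
#' initialization the initialization is returned (flagged), so the reported
#' residual sum of squares never exceeds the warm start's.
#'
#' @inheritParams fit_isotropic_fwe
#' @return object of classes \code{bitensor_fit}, \code{bitensor_voxel}
#'   with elements \code{S0}, \code{f} (FWVF), \code{D_fluid},
#'   \code{D_tissue} (mm^2/s), \code{rss}, \code{converged}, \code{niter},
#'   \code{method}.
#' @examples
#' sch <- make_scheme("hcpa")
#' vox <- bitensor_voxel(100, 0.3, axial_tensor(c(0, 0, 1), 3.5e-3, 2.5e-3),
#'                       axial_tensor(c(0, 1, 0), 1.5e-3, 0.4e-3))
#' fit <- fit_bitensor(simulate_signal(vox, sch), sch)
#' coef(fit)["f"]
#' @export
fit_bitensor <- function(signal, scheme, config = fit_config()) {
  prep <- fit_prepare(signal, scheme)
  iso <- iso_stage(prep, config)
  Df0 <- diag(3) * config$d_free * DSCALE
  best <- aniso_stage(prep, config, iso$f, iso$Dt, Df0)
  for (fs in config$extra_f_starts) {
    cand <- aniso_stage(prep, config, fs, iso$Dt, Df0)
    if (cand$rss < best$rss) best <- cand
  }
  if (best$rss > iso$rss) {
    # monotone-refinement guarantee: fall back to the isotropic warm start
    return(finish_fit(prep, scheme, iso$f, iso$Dt / DSCALE,
                      diag(3) * config$d_free, iso$rss,
                      converged = FALSE, niter = best$niter,
                      method = "fallback_isotropic"))
  }
  finish_fit(prep, scheme, best$f, best$Dt / DSCALE, best$Df / DSCALE,
             best$rss, best$converged, best$niter, "anisotropic")
}

#' @export
print.bitensor_fit <- function(x, ...) {
  fm <- tensor_metrics(x$D_fluid)
  tm <- tensor_metrics(x$D_tissue)
  cat("Bi-tensor fit (", x$method, ")\n", sep = "")
  cat(sprintf("  S0 = %.4g, FWVF (f) = %.4f\n", x$S0, x$f))
  cat(sprintf("  fluid : AD %.3e  RD %.3e  MD %.3e  FA %.3f (mm^2/s)\n",
              fm$AD, fm$RD, fm$MD, fm$FA))
  cat(sprintf("  tissue: AD %.3e  RD %.3e  MD %.3e  FA %.3f (mm^2/s)\n",
              tm$AD, tm$RD, tm$MD, tm$FA))
  cat(sprintf("  RSS %.4g, converged: %s, iterations: %d\n",
              x$rss, x$converged, x$niter))
  invisible(x)
}

#' @export
coef.bitensor_fit <- function(object, ...) {
  fm <- tensor_metrics(object$D_fluid)
  tm <- tensor_metrics(object$D_tissue)
  c(S0 = object$S0, f = object$f,
    FWAD = fm$AD, FWRD = fm$RD, FWMD = fm$MD, FWFA = fm$FA,
    tAD = tm$AD, tRD = tm$RD, tMD = tm$MD, tFA = tm$FA)
}

#' @export
predict.bitensor_fit <- function(object, scheme = object$scheme, ...) {
  simulate_signal(object, scheme)
}

#' @export
fitted.bitensor_fit <- function(object, ...) {
  simulate_signal(object, object$scheme)
}

#' @export
residuals.bitensor_fit <- function(object, ...) {
  object$signal - fitted(object)
}
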