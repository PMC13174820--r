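# DTI-ALPS: diffusivity along the perivascular space.
#
# At the level of the lateral ventricle bodies, medullary veins run
# left-right (x) while projection fibers run inferior-superior (z) and
# association fibers anterior-posterior (y). Diffusivity along x in both
# fiber ROIs is attributed to perivascular fluid; the index normalizes it
# by the diffusivities perpendicular to both the fibers and the vessels:
#
#   ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)

#' Specify projection/association ROIs for the ALPS index
#'
#' @param proj_voxels,assoc_voxels integer matrices (n x 3) of voxel indices
#'   (projection-fiber ROI: dominant fiber axis z; association-fiber ROI:
#'   dominant axis y). Must be nonempty and disjoint.
#' @param side label, one of \code{"left"}, \code{"right"},
#'   \code{"bilateral"}.
#' @return object of class \code{alps_roi}.
#' @export
alps_roi <- function(proj_voxels, assoc_voxels, side = "bilateral") {
  proj_voxels <- as.matrix(proj_voxels)
  assoc_voxels <- as.matrix(assoc_voxels)
  if (!nrow(proj_voxels) || !nrow(assoc_voxels))
    stop("ALPS ROIs must be nonempty", call. = FALSE)
  if (ncol(proj_voxels) != 3L || ncol(assoc_voxels) != 3L)
    stop("ROI voxel sets must be n x 3 index matrices", call. = FALSE)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  if (length(intersect(key(proj_voxels), key(assoc_voxels))))
    stop("projection and association ROIs must be disjoint", call. = FALSE)
  structure(list(proj = proj_voxels, assoc = assoc_voxels,
                 side = match.arg(side, c("left", "right", "bilateral"))),
            class = "alps_roi")
}

roi_mean <- function(vol, vox, what) {
  v <- vol[vox]
  v <- v[is.finite(v)]
  if (!length(v))
    stop("ALPS ROI (", what, ") has no finite voxels", call. = FALSE)
  if (any(v < -1e-12)) {
    warning("negative diffusivities in ", what, " clamped to 0")
    v <- pmax(v, 0)
  }
  mean(v)
}

#' Compute the DTI-ALPS index
#'
#' @param Dxx,Dyy,Dzz 3-D diffusivity volumes (mm^2/s) on a common grid,
#'   e.g. from \code{\link{fit_dti_volume}} (conventional single-tensor fit,
#'   the default source) or the tissue-tensor maps of
#'   \code{\link{fit_volume}} (\code{tDxx}/\code{tDyy}/\code{tDzz}).
#' @param rois an \code{\link{alps_roi}}, or a list of them (e.g. left and
#'   right); with several ROIs the bilateral index is the arithmetic mean of
#'   the per-ROI indices.
#' @return object of class \code{alps_result}: ROI-mean diffusivities and
#'   \code{alps_index}. For a list input, \code{$per_roi} holds the
#'   unilateral results.
#' @export
compute_alps <- function(Dxx, Dyy, Dzz, rois) {
  if (!identical(dim(Dxx), dim(Dyy)) || !identical(dim(Dxx), dim(Dzz)))
    stop("diffusivity maps must share a grid", call. = FALSE)
  if (inherits(rois, "alps_roi")) {
    Dxx_p <- roi_mean(Dxx, rois$proj, "Dxx projection")
    Dxx_a <- roi_mean(Dxx, rois$assoc, "Dxx association")
    Dyy_p <- roi_mean(Dyy, rois$proj, "Dyy projection")
    Dzz_a <- roi_mean(Dzz, rois$assoc, "Dzz association")
    res <- list(Dxx_proj = Dxx_p, Dxx_assoc = Dxx_a,
                Dyy_proj = Dyy_p, Dzz_assoc = Dzz_a,
                alps_index = mean(c(Dxx_p, Dxx_a)) / mean(c(Dyy_p, Dzz_a)),
                side = rois$side)
    class(res) <- "alps_result"
    return(res)
  }
  per <- lapply(rois, function(r) compute_alps(Dxx, Dyy, Dzz, r))
  res <- list(alps_index = mean(vapply(per, `[[`, 0, "alps_index")),
              side = "bilateral", per_roi = per)
  class(res) <- "alps_result"
  res
}

#' @export
print.alps_result <- function(x, ...) {
  cat("DTI-ALPS (", x$side, "): index = ", format(x$alps_index), "\n",
      sep = "")
  if (!is.null(x$Dxx_proj))
    cat(sprintf("  Dxx proj %.3e  Dxx assoc %.3e  Dyy proj %.3e  Dzz assoc %.3e\n",
                x$Dxx_proj, x$Dxx_assoc, x$Dyy_proj, x$Dzz_assoc))
  invisible(x)
}

#' Deterministic phantom ROI placement for ALPS
#'
#' Places two disjoint cubic ROIs (projection and association) inside a
#' grid, symmetric about the mid-sagittal plane of the grid.
#'
#' @param dims grid dimensions (length 3).
#' @param roi_size edge length of each cubic ROI in voxels.
#' @param offset voxel offset of the projection ROI corner from the grid
#'   center; the association ROI is placed \code{roi_size + 1} voxels
#'   posterior (y) to it.
#' @return an \code{\link{alps_roi}}.
#' @export
make_alps_phantom_rois <- function(dims, roi_size = 2L,
                                   offset = c(1L, 1L, 1L)) {
  dims <- as.integer(dims)
  roi_size <- as.integer(roi_size)
  ctr <- pmax(dims %/% 2L, 1L)
  corner_p <- ctr + as.integer(offset)
  corner_a <- corner_p + c(0L, roi_size + 1L, 0L)
  cube <- function(corner) {
    rng <- lapply(1:3, function(a) corner[a] + seq_len(roi_size) - 1L)
    if (any(vapply(1:3, function(a) rng[[a]][roi_size] > dims[a] ||
                     rng[[a]][1] < 1L, TRUE)))
      stop("grid too small for the requested ALPS phantom ROIs",
           call. = FALSE)
    as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  }
  alps_roi(cube(corner_p), cube(corner_a))
}
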