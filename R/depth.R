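# Superficial-white-matter depth via Laplacian distance mapping, and
# propagation of cortical ROI labels into superficial WM by k-NN.

lin_index <- function(vox, dims) {
  vox[, 1] + dims[1] * (vox[, 2] - 1L) + dims[1] * dims[2] * (vox[, 3] - 1L)
}

# pairwise Euclidean distances (mm) between two voxel coordinate sets
vox_dist <- function(a, b, spacing) {
  am <- sweep(as.matrix(a), 2, spacing, `*`)
  bm <- sweep(as.matrix(b), 2, spacing, `*`)
  outer(rowSums(am^2), rep(1, nrow(bm))) +
    outer(rep(1, nrow(am)), rowSums(bm^2)) - 2 * tcrossprod(am, bm)
}

min_dist_mm <- function(a, b, spacing) {
  sqrt(pmax(apply(vox_dist(a, b, spacing), 1, min), 0))
}

#' Laplacian depth map of superficial white matter
#'
#' Solves the Laplace equation over the WM interior with Dirichlet
#' conditions (0 at the gray-matter boundary, 1 at the deep boundary) on a
#' 6-neighbor stencil, then converts the harmonic potential phi to metric
#' depth without streamline integration:
#' depth = phi * (d_GM + d_deep), where d_GM and d_deep are the Euclidean
#' distances (mm) to the nearest voxel of each boundary — the per-voxel
#' total path length between boundaries. On slab geometry this equals the
#' streamline depth. WM voxels in regions touching neither boundary are
#' flagged missing (NA).
#'
#' @param wm_mask 3-D binary WM mask.
#' @param gm_boundary_mask 3-D binary mask of the gray matter-WM boundary
#'   (depth 0).
#' @param deep_boundary_mask 3-D binary mask of the deep boundary (full
#'   depth).
#' @param spacing voxel spacing in mm.
#' @return object of class \code{depth_map}: list with \code{depth} (mm, NA
#'   outside WM and in unreachable regions), \code{phi} (the harmonic
#'   potential in [0, 1]), and \code{spacing}.
#' @export
laplace_depth <- function(wm_mask, gm_boundary_mask, deep_boundary_mask,
                          spacing = c(1, 1, 1)) {
  wm <- array(as.logical(wm_mask), dim = dim(as.array(wm_mask)))
  gmb <- array(as.logical(gm_boundary_mask), dim = dim(wm))
  dpb <- array(as.logical(deep_boundary_mask), dim = dim(wm))
  if (!any(gmb) || !any(dpb))
    stop("both boundary masks must be nonempty", call. = FALSE)
  dims <- dim(wm)
  domain <- wm | gmb | dpb
  interior <- domain & !gmb & !dpb

  phi <- array(NA_real_, dims)
  phi[gmb] <- 0
  phi[dpb] <- 1

  int_idx <- which(interior)
  if (length(int_idx)) {
    # 6-neighbor graph over the domain, spacing-weighted
    row_of <- array(0L, dims)
    row_of[int_idx] <- seq_along(int_idx)
    coord <- arrayInd(int_idx, dims)
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    rhs <- numeric(length(int_idx))
    diagw <- numeric(length(int_idx))
    for (a in 1:3) for (s in c(-1L, 1L)) {
      nb <- coord
      nb[, a] <- nb[, a] + s
      ok <- nb[, a] >= 1L & nb[, a] <= dims[a]
      w <- 1 / spacing[a]^2
      nlin <- lin_index(nb[ok, , drop = FALSE], dims)
      in_dom <- domain[nlin]
      rows <- which(ok)[in_dom]
      nlin <- nlin[in_dom]
      diagw[rows] <- diagw[rows] + w
      is_int <- interior[nlin]
      # interior neighbor: off-diagonal entry; boundary neighbor: RHS
      trip_i <- c(trip_i, rows[is_int])
      trip_j <- c(trip_j, row_of[nlin[is_int]])
      trip_x <- c(trip_x, rep(-w, sum(is_int)))
      bnd <- which(!is_int)
      rhs[rows[bnd]] <- rhs[rows[bnd]] + w * phi[nlin[bnd]]
    }
    A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = rep(length(int_idx), 2)) +
      Matrix::Diagonal(x = diagw)
    # a voxel is solvable only if its interior component touches a Dirichlet
    # boundary; detect by BFS seeded at rows that received boundary RHS
    reach <- rhs != 0
    adj <- split(trip_j, factor(trip_i, levels = seq_along(int_idx)))
    radj <- split(trip_i, factor(trip_j, levels = seq_along(int_idx)))
    frontier <- which(reach)
    while (length(frontier)) {
      nxt <- unique(c(unlist(adj[frontier], use.names = FALSE),
                      unlist(radj[frontier], use.names = FALSE)))
      nxt <- nxt[!reach[nxt]]
      reach[nxt] <- TRUE
      frontier <- nxt
    }
    solve_rows <- which(reach)
    if (length(solve_rows)) {
      sol <- as.numeric(Matrix::solve(A[solve_rows, solve_rows,
                                        drop = FALSE], rhs[solve_rows]))
      phi[int_idx[solve_rows]] <- pmin(pmax(sol, 0), 1)
    }
    if (any(!reach))
      warning(sum(!reach), " WM voxel(s) touch neither boundary; ",
              "depth flagged missing")
  }

  depth <- array(NA_real_, dims)
  fin <- which(domain & is.finite(phi))
  if (length(fin)) {
    co <- arrayInd(fin, dims)
    d0 <- min_dist_mm(co, arrayInd(which(gmb), dims), spacing)
    d1 <- min_dist_mm(co, arrayInd(which(dpb), dims), spacing)
    depth[fin] <- phi[fin] * (d0 + d1)
  }
  structure(list(depth = depth, phi = phi, spacing = spacing),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  d <- x$depth[is.finite(x$depth)]
  cat("Depth map:", length(d), "voxels, range",
      sprintf("%.2f-%.2f mm\n", min(d), max(d)))
  invisible(x)
}

#' Propagate cortical ROI labels into superficial white matter
#'
#' Every WM voxel with depth at most \code{max_depth} receives the majority
#' label among its \code{k} nearest labeled boundary voxels (Euclidean
#' distance in mm); ties break toward the lowest label. Deeper or
#' unreachable voxels stay unlabeled.
#'
#' @param atlas 3-D integer label volume defined on (or near) the cortical
#'   boundary; 0 = background.
#' @param depth a \code{\link{laplace_depth}} result (or a 3-D depth array
#'   in mm).
#' @param max_depth depth gate in mm (default 5).
#' @param k number of neighbors (default 5).
#' @param spacing voxel spacing in mm.
#' @return 3-D integer label volume over superficial WM.
#' @export
propagate_labels_knn <- function(atlas, depth, max_depth = 5, k = 5L,
                                 spacing = c(1, 1, 1)) {
  atlas <- as.array(atlas)
  dmap <- if (inherits(depth, "depth_map")) depth$depth else as.array(depth)
  if (!identical(dim(atlas), dim(dmap)))
    stop("atlas and depth map grids disagree", call. = FALSE)
  src <- which(atlas > 0)
  if (!length(src))
    stop("no labeled boundary voxels to propagate", call. = FALSE)
  src_co <- arrayInd(src, dim(atlas))
  src_lab <- atlas[src]
  trg <- which(is.finite(dmap) & dmap <= max_depth)
  out <- array(0L, dim(atlas))
  if (!length(trg)) return(out)
  trg_co <- arrayInd(trg, dim(atlas))
  d2 <- vox_dist(trg_co, src_co, spacing)
  k <- min(k, length(src))
  for (i in seq_along(trg)) {
    nn <- order(d2[i, ])[seq_len(k)]
    tab <- table(src_lab[nn])
    out[trg[i]] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}
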