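# Perivascular-space (pAs) component morphometry: connected-component
# labeling, diameter/elongation estimation, false-positive filtering, ROI
# assignment and n-largest selection.

conn_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = off[rowSums(abs(off)) == 1, , drop = FALSE],
         "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
         "26" = off,
         stop("connectivity must be 6, 18 or 26", call. = FALSE))
}

# BFS flood fill over a logical 3-D array; returns integer label array.
# Seeds are visited in increasing linear-index order, so labels are
# deterministic.
flood_label <- function(mask, connectivity) {
  dims <- dim(mask)
  off <- conn_offsets(connectivity)
  lab <- array(0L, dims)
  nlab <- 0L
  for (seed in which(mask)) {
    if (lab[seed] != 0L) next
    nlab <- nlab + 1L
    lab[seed] <- nlab
    frontier <- matrix(arrayInd(seed, dims), 1L)
    while (nrow(frontier)) {
      nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                     drop = FALSE] +
        off[rep(seq_len(nrow(off)), nrow(frontier)), , drop = FALSE]
      keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[keep, , drop = FALSE]
      if (!nrow(nb)) break
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1L) + dims[1] * dims[2] *
        (nb[, 3] - 1L)
      new <- !duplicated(lin) & mask[lin] & lab[lin] == 0L
      lin <- lin[new]
      lab[lin] <- nlab
      frontier <- nb[new, , drop = FALSE]
    }
  }
  lab
}

#' Label connected perivascular-space components
#'
#' Flood-fill labeling of a binary pAs mask, with per-component morphology
#' (volume, equivalent and medial-axis diameter, elongation, centroid).
#' Components are ordered by decreasing volume (ties by first voxel index),
#' which makes labels deterministic.
#'
#' @param pas_mask 3-D binary array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param spacing voxel spacing in mm (length 3).
#' @return object of class \code{pas_components}: a data frame with columns
#'   \code{id}, \code{n_voxels}, \code{volume_mm3}, \code{diameter_mm},
#'   \code{diameter_flag}, \code{elongation}, \code{centroid_x/y/z} (mm),
#'   \code{roi_label} (NA until assigned), \code{kept}, \code{reason};
#'   voxel coordinate matrices in \code{attr(, "voxels")}.
#' @export
label_components <- function(pas_mask, connectivity = 26L,
                             spacing = c(1, 1, 1)) {
  mask <- array(as.logical(pas_mask), dim = dim(as.array(pas_mask)))
  mask[is.na(mask)] <- FALSE
  lab <- flood_label(mask, connectivity)
  n <- max(lab)
  vox <- vector("list", n)
  if (n > 0) {
    ind <- arrayInd(which(lab > 0L), dim(mask))
    lv <- lab[lab > 0L]
    for (i in seq_len(n)) vox[[i]] <- ind[lv == i, , drop = FALSE]
    dm <- dim(mask)
    ord <- order(-vapply(vox, nrow, 0L),
                 vapply(vox, function(m)
                   min(m[, 1] + dm[1] * (m[, 2] - 1) +
                         dm[1] * dm[2] * (m[, 3] - 1)), 0))
    vox <- vox[ord]
  }
  vvol <- prod(spacing)
  nv <- vapply(vox, nrow, 0L)
  dia <- lapply(vox, estimate_diameter, spacing = spacing, dims = dim(mask))
  df <- data.frame(
    id = seq_len(n),
    n_voxels = nv,
    volume_mm3 = nv * vvol,
    diameter_mm = vapply(dia, `[[`, 0, "diameter"),
    diameter_flag = vapply(dia, `[[`, TRUE, "flagged"),
    elongation = vapply(vox, elongation_ratio, 0, spacing = spacing),
    centroid_x = vapply(vox, function(m) mean(m[, 1]) * spacing[1], 0),
    centroid_y = vapply(vox, function(m) mean(m[, 2]) * spacing[2], 0),
    centroid_z = vapply(vox, function(m) mean(m[, 3]) * spacing[3], 0),
    roi_label = rep(NA_integer_, n),
    roi_tie = rep(FALSE, n),
    kept = rep(TRUE, n),
    reason = rep(NA_character_, n)
  )
  structure(df, voxels = vox, spacing = spacing, dims = dim(mask),
            connectivity = connectivity,
            class = c("pas_components", "data.frame"))
}

#' @export
print.pas_components <- function(x, ...) {
  cat("pAs components:", nrow(x), "(kept:", sum(x$kept), ")\n")
  NextMethod()
}

#' Medial-axis diameter of a component
#'
#' Definition used throughout: twice the mean of the interior Euclidean
#' distance-transform values over the component's medial-axis voxels, where
#' the medial axis is approximated by voxels whose interior distance is a
#' local maximum within their 26-neighborhood. A single-voxel component is
#' assigned the smallest voxel spacing and flagged.
#'
#' @param voxels n x 3 integer matrix of voxel indices.
#' @param spacing voxel spacing in mm.
#' @param dims grid dimensions (defaults to the component bounding box
#'   padded by one voxel, which is sufficient for the distance transform).
#' @return list with \code{diameter} (mm) and \code{flagged}.
#' @export
estimate_diameter <- function(voxels, spacing = c(1, 1, 1), dims = NULL) {
  voxels <- as.matrix(voxels)
  if (!nrow(voxels)) stop("empty component", call. = FALSE)
  if (nrow(voxels) == 1L)
    return(list(diameter = min(spacing), flagged = TRUE))
  dt <- interior_distance(voxels, spacing)
  # medial axis: local maxima of the interior distance among 26-neighbors
  key <- paste(voxels[, 1], voxels[, 2], voxels[, 3])
  off <- conn_offsets(26L)
  ridge <- vapply(seq_len(nrow(voxels)), function(i) {
    nb <- sweep(off, 2, voxels[i, ], `+`)
    j <- match(paste(nb[, 1], nb[, 2], nb[, 3]), key)
    all(dt[i] >= dt[stats::na.omit(j)])
  }, TRUE)
  list(diameter = 2 * mean(dt[ridge]), flagged = FALSE)
}

# distance (mm) from each component voxel center to the nearest
# non-component voxel center, computed over the padded bounding box
interior_distance <- function(voxels, spacing) {
  lo <- apply(voxels, 2, min) - 1L
  hi <- apply(voxels, 2, max) + 1L
  grid <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                z = lo[3]:hi[3]))
  inside <- !is.na(match(paste(grid[, 1], grid[, 2], grid[, 3]),
                         paste(voxels[, 1], voxels[, 2], voxels[, 3])))
  bg <- grid[!inside, , drop = FALSE]
  vapply(seq_len(nrow(voxels)), function(i) {
    d <- sweep(bg, 2, voxels[i, ], `-`)
    sqrt(min(colSums((t(d) * spacing)^2)))
  }, 0)
}

# principal-axis length over mean orthogonal width, from the voxel-cloud
# covariance; >= 1 by construction, 1 for an isotropic cloud
elongation_ratio <- function(voxels, spacing = c(1, 1, 1)) {
  if (nrow(voxels) == 1L) return(1)
  xyz <- sweep(as.matrix(voxels), 2, spacing, `*`)
  ev <- eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values
  # half-voxel jitter keeps widths positive for planar/linear clouds
  len <- sqrt(pmax(ev, 0)) + min(spacing) / 2
  max(len[1] / mean(len[2:3]), 1)
}

#' False-positive exclusion rules for pAs components
#'
#' @param elongation_min components with elongation below this are "round"
#'   (lacunes, small WMHs) and removed; default 1.5.
#' @param wmh_overlap_max maximum tolerated fraction of component voxels
#'   inside the WMH mask; default 0.5.
#' @param volume_min_voxels,volume_max_mm3 size gates; defaults 2 voxels
#'   and 3000 mm^3.
#' @param predicates optional named list of extra exclusion predicates,
#'   each a \code{function(component_row, voxels)} returning TRUE to remove
#'   (e.g. clustering-density or anatomical-location rules); defaults off.
#' @return list of class \code{pas_filter_config}.
#' @export
pas_filter_config <- function(elongation_min = 1.5, wmh_overlap_max = 0.5,
                              volume_min_voxels = 2L, volume_max_mm3 = 3000,
                              predicates = list()) {
  structure(list(elongation_min = elongation_min,
                 wmh_overlap_max = wmh_overlap_max,
                 volume_min_voxels = volume_min_voxels,
                 volume_max_mm3 = volume_max_mm3,
                 predicates = predicates),
            class = "pas_filter_config")
}

#' Remove false-positive pAs components
#'
#' Applies, in order: WMH-overlap, roundness (elongation), size gates, then
#' any user predicates. Every removal carries a machine-readable reason.
#' Filtering is idempotent: re-filtering the kept set removes nothing.
#'
#' @param components a \code{\link{label_components}} result.
#' @param wmh_mask 3-D binary WMH mask on the same grid (or NULL).
#' @param rules a \code{\link{pas_filter_config}}.
#' @return the components object with \code{kept}/\code{reason} updated.
#' @export
filter_false_positives <- function(components, wmh_mask = NULL,
                                   rules = pas_filter_config()) {
  vox <- attr(components, "voxels")
  dims <- attr(components, "dims")
  if (!is.null(wmh_mask)) {
    wmh_mask <- array(as.logical(wmh_mask), dim = dim(as.array(wmh_mask)))
    if (!identical(dim(wmh_mask), dims))
      stop("WMH mask grid does not match the components", call. = FALSE)
  }
  for (i in seq_len(nrow(components))) {
    if (!components$kept[i]) next
    v <- vox[[i]]
    reason <- NULL
    if (!is.null(wmh_mask)) {
      ov <- mean(wmh_mask[v])
      if (ov > rules$wmh_overlap_max) reason <- "wmh_overlap"
    }
    if (is.null(reason) && components$n_voxels[i] < rules$volume_min_voxels)
      reason <- "too_small"
    if (is.null(reason) && components$volume_mm3[i] > rules$volume_max_mm3)
      reason <- "too_large"
    if (is.null(reason) && components$elongation[i] < rules$elongation_min)
      reason <- "round"
    if (is.null(reason))
      for (nm in names(rules$predicates))
        if (isTRUE(rules$predicates[[nm]](components[i, ], v))) {
          reason <- nm
          break
        }
    if (!is.null(reason)) {
      components$kept[i] <- FALSE
      components$reason[i] <- reason
    }
  }
  components
}

#' Assign components to atlas ROIs by maximal overlap
#'
#' A component receives the ROI label with the largest voxel overlap; zero
#' overlap leaves it unassigned (NA). Exact ties break toward the lowest
#' label id and are flagged in \code{roi_tie}.
#'
#' @param components a \code{pas_components} object.
#' @param roi_labels 3-D integer label volume (0 = background).
#' @return the components object with \code{roi_label} filled in.
#' @export
assign_to_rois <- function(components, roi_labels) {
  roi_labels <- as.array(roi_labels)
  if (!identical(dim(roi_labels), attr(components, "dims")))
    stop("ROI label volume grid does not match the components",
         call. = FALSE)
  vox <- attr(components, "voxels")
  for (i in seq_len(nrow(components))) {
    labs <- roi_labels[vox[[i]]]
    labs <- labs[labs > 0]
    if (!length(labs)) next
    tab <- table(labs)
    top <- tab[tab == max(tab)]
    components$roi_label[i] <- as.integer(names(top)[1])
    components$roi_tie[i] <- length(top) > 1L
  }
  components
}

#' Select the n largest components per ROI
#'
#' Selection is by volume, descending, with exact ties broken by component
#' id (deterministic). ROIs holding fewer than \code{n} kept components
#' return all of them; the shortfall is recorded.
#'
#' @param components a filtered, ROI-assigned \code{pas_components} object.
#' @param n number of components per ROI (default 4, the partial-volume
#'   guard: larger components exceed the DWI voxel size).
#' @return the components object with a logical \code{selected} column;
#'   \code{attr(, "shortfall")} is a data frame of ROIs with fewer than
#'   \code{n} components.
#' @export
select_n_largest <- function(components, n = 4L) {
  components$selected <- FALSE
  short <- NULL
  for (r in sort(unique(stats::na.omit(components$roi_label)))) {
    i <- which(components$kept & !is.na(components$roi_label) &
                 components$roi_label == r)
    i <- i[order(-components$volume_mm3[i], components$id[i])]
    take <- utils::head(i, n)
    components$selected[take] <- TRUE
    if (length(i) < n)
      short <- rbind(short, data.frame(roi_label = r,
                                       n_available = length(i)))
  }
  attr(components, "shortfall") <- short
  components
}
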