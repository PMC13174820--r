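# Subject-level feature extraction: ROI means of pAs and WM maps, and the
# classifier feature-set definitions.

#' ROI-level pAs diffusivity metrics
#'
#' Unweighted voxel means of FWAD and FWVF over the voxels of the selected
#' components in each ROI ("averaged across voxels"). The whole-brain value
#' pools the voxels of the selected components of all ROIs (a config switch
#' re-selects the n largest globally instead).
#'
#' @param maps a \code{\link{fit_volume}} result (\code{scalar_maps}).
#' @param components a \code{pas_components} object after
#'   \code{\link{select_n_largest}}.
#' @param global_reselect if TRUE, the whole-brain metric re-applies the
#'   n-largest rule across all kept components regardless of ROI; default
#'   FALSE (pool the per-ROI selections).
#' @param n used only when \code{global_reselect = TRUE}.
#' @return list: \code{per_roi} data frame (\code{roi_label},
#'   \code{n_components}, \code{n_voxels}, \code{pas_FWAD},
#'   \code{pas_FWVF}) and \code{whole_brain} named vector. ROIs with no
#'   selected components are reported with NA and counted in
#'   \code{missing_rois}.
#' @export
pas_roi_metrics <- function(maps, components, global_reselect = FALSE,
                            n = 4L) {
  stopifnot(inherits(maps, "scalar_maps"))
  vox <- attr(components, "voxels")
  rois <- sort(unique(stats::na.omit(components$roi_label)))
  per <- data.frame(roi_label = rois, n_components = NA_integer_,
                    n_voxels = NA_integer_, pas_FWAD = NA_real_,
                    pas_FWVF = NA_real_)
  all_vox <- NULL
  for (ri in seq_along(rois)) {
    i <- which(components$selected & !is.na(components$roi_label) &
                 components$roi_label == rois[ri])
    if (!length(i)) next
    v <- do.call(rbind, vox[i])
    per$n_components[ri] <- length(i)
    per$n_voxels[ri] <- nrow(v)
    per$pas_FWAD[ri] <- mean(maps$maps$FWAD[v], na.rm = TRUE)
    per$pas_FWVF[ri] <- mean(maps$maps$FWVF[v], na.rm = TRUE)
    all_vox <- rbind(all_vox, v)
  }
  if (global_reselect) {
    i <- which(components$kept)
    i <- i[order(-components$volume_mm3[i], components$id[i])]
    i <- utils::head(i, n)
    all_vox <- do.call(rbind, vox[i])
  }
  wb <- if (is.null(all_vox)) c(pas_FWAD = NA_real_, pas_FWVF = NA_real_)
  else c(pas_FWAD = mean(maps$maps$FWAD[all_vox], na.rm = TRUE),
         pas_FWVF = mean(maps$maps$FWVF[all_vox], na.rm = TRUE))
  miss <- per$roi_label[is.na(per$pas_FWVF)]
  if (length(miss))
    message("ROI(s) without selected pAs components: ",
            paste(miss, collapse = ", "))
  list(per_roi = per, whole_brain = wb, missing_rois = miss)
}

#' White-matter FWVF with lesion and pAs exclusion
#'
#' Mean free-water volume fraction over WM voxels after removing all WMH
#' and pAs voxels, per superficial-WM ROI label and for the whole WM.
#'
#' @param maps a \code{scalar_maps} object.
#' @param wm_mask,wmh_mask,pas_mask 3-D binary masks on the map grid
#'   (\code{wmh_mask}/\code{pas_mask} may be NULL).
#' @param roi_labels 3-D integer label volume of superficial WM (e.g. from
#'   \code{\link{propagate_labels_knn}}); NULL for whole-WM only.
#' @return list: \code{per_roi} data frame (\code{roi_label},
#'   \code{n_voxels}, \code{wm_FWVF}; NA where the effective ROI is empty)
#'   and \code{whole_brain} scalar.
#' @export
wm_fwvf <- function(maps, wm_mask, wmh_mask = NULL, pas_mask = NULL,
                    roi_labels = NULL) {
  stopifnot(inherits(maps, "scalar_maps"))
  fw <- maps$maps$FWVF
  eff <- array(as.logical(wm_mask), dim = dim(fw))
  if (!is.null(wmh_mask)) eff <- eff & !as.logical(wmh_mask)
  if (!is.null(pas_mask)) eff <- eff & !as.logical(pas_mask)
  eff <- eff & is.finite(fw)
  wb <- if (any(eff)) mean(fw[eff]) else NA_real_
  per <- NULL
  if (!is.null(roi_labels)) {
    roi_labels <- as.array(roi_labels)
    rois <- sort(unique(roi_labels[roi_labels > 0]))
    per <- data.frame(roi_label = rois, n_voxels = NA_integer_,
                      wm_FWVF = NA_real_)
    for (ri in seq_along(rois)) {
      sel <- eff & roi_labels == rois[ri]
      per$n_voxels[ri] <- sum(sel)
      if (any(sel)) per$wm_FWVF[ri] <- mean(fw[sel])
    }
  }
  list(per_roi = per, whole_brain = wb)
}

feature_set_columns <- list(
  pas = c("pas_FWVF_precuneus", "pas_FWAD_precuneus",
          "pas_FWVF_adsig", "pas_FWAD_adsig",
          "pas_FWVF_wholebrain", "pas_FWAD_wholebrain"),
  wm = c("wm_FWVF_precuneus", "wm_FWVF_adsig", "wm_FWVF_wholebrain"),
  pvs = "alps",
  abeta_pet = c("abeta_suvr_precuneus", "abeta_suvr_adsig",
                "abeta_suvr_wholebrain"),
  tau_pet = c("tau_suvr_precuneus", "tau_suvr_adsig",
              "tau_suvr_wholebrain")
)

#' Classifier feature sets from subject-level features
#'
#' Builds the named feature matrices used for classification: \code{pas}
#' (6 columns: FWVF and FWAD in precuneus, AD-signature, whole brain),
#' \code{wm} (3 columns of WM-FWVF), \code{pvs} (the ALPS index),
#' \code{pas_wm}, \code{all}, and — when a PET SUVR table is supplied —
#' \code{abeta_pet} and \code{tau_pet} (3 columns each). Column order is
#' fixed; rows with missing values are dropped per set (listwise deletion),
#' so a subject missing only ALPS is excluded from \code{pvs}-based
#' analyses but retained elsewhere.
#'
#' @param features data frame of subject-level features (one row per
#'   subject) with the column names listed above.
#' @param pet optional data frame with the PET SUVR columns.
#' @return named list of numeric matrices; each carries attribute
#'   \code{"rows"} with the retained row indices of \code{features}.
#' @export
build_feature_sets <- function(features, pet = NULL) {
  if (!is.null(pet)) features <- cbind(features, pet)
  sets <- list(pas = feature_set_columns$pas, wm = feature_set_columns$wm,
               pvs = feature_set_columns$pvs,
               pas_wm = c(feature_set_columns$pas, feature_set_columns$wm),
               all = c(feature_set_columns$pas, feature_set_columns$wm,
                       feature_set_columns$pvs))
  if (!is.null(pet)) {
    sets$abeta_pet <- feature_set_columns$abeta_pet
    sets$tau_pet <- feature_set_columns$tau_pet
  }
  out <- list()
  for (nm in names(sets)) {
    cols <- sets[[nm]]
    if (!all(cols %in% names(features)))
      stop("feature set '", nm, "' is fully or partly absent from the ",
           "feature table", call. = FALSE)
    m <- as.matrix(features[, cols, drop = FALSE])
    keep <- stats::complete.cases(m)
    if (!any(keep))
      stop("feature set '", nm, "' has no complete cases", call. = FALSE)
    m <- m[keep, , drop = FALSE]
    attr(m, "rows") <- which(keep)
    out[[nm]] <- m
  }
  out
}
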