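# NIfTI and sidecar I/O. Volumes are handled as plain arrays internally;
# RNifti carries the on-disk format and voxel dimensions.

#' Read a 4-D DWI volume (NIfTI)
#'
#' @param path NIfTI file.
#' @return list: \code{data} (4-D array), \code{spacing} (mm, length 3).
#' @export
read_dwi <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}

#' Read a 3-D mask or label volume (NIfTI)
#'
#' @param path NIfTI file.
#' @param logical coerce to logical (default) or keep integer labels.
#' @return 3-D array.
#' @export
read_mask <- function(path, logical = TRUE) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img)[1:3])
  if (logical) a > 0 else array(as.integer(round(a)), dim = dim(a))
}

#' Write a 3-D/4-D array as NIfTI
#'
#' @param data numeric array.
#' @param path output file (.nii or .nii.gz).
#' @param spacing voxel spacing in mm.
#' @export
write_volume <- function(data, path, spacing = c(1, 1, 1)) {
  attr(data, "pixdim") <- c(spacing, rep(1, length(dim(data)) - 3L))
  RNifti::writeNifti(RNifti::asNifti(data, datatype = "double"), path)
  invisible(path)
}

#' Write a scalar map set to a directory
#'
#' One NIfTI per map plus a JSON sidecar recording the configuration, a
#' hash of the acquisition scheme, and convergence statistics.
#'
#' @param maps a \code{scalar_maps} object.
#' @param dir output directory (created if needed).
#' @param scheme the \code{acq_scheme} used for fitting (for the sidecar).
#' @param config the \code{fit_config} used (for the sidecar).
#' @return invisibly, the sidecar path.
#' @export
write_scalar_maps <- function(maps, dir, scheme = NULL, config = NULL) {
  stopifnot(inherits(maps, "scalar_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(maps$maps))
    write_volume(maps$maps[[nm]], file.path(dir, paste0(nm, ".nii.gz")),
                 maps$spacing)
  write_volume(maps$provenance, file.path(dir, "provenance.nii.gz"),
               maps$spacing)
  sidecar <- list(
    maps = names(maps$maps),
    spacing_mm = maps$spacing,
    n_fitted = sum(maps$provenance > 0L),
    n_fallback = sum(maps$provenance == 2L),
    n_degenerate = maps$n_degenerate,
    scheme_hash = if (!is.null(scheme))
      scheme_hash(scheme) else NULL,
    config = if (!is.null(config)) unclass(config)[
      c("d_free", "tissue_bounds", "fluid_bounds", "md_prior_weight",
        "bound_weight", "maxit")] else NULL
  )
  path <- file.path(dir, "sidecar.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a scalar map set from a directory written by write_scalar_maps
#' @param dir directory containing the per-map NIfTIs.
#' @return a \code{scalar_maps} object.
#' @export
read_scalar_maps <- function(dir) {
  maps <- list()
  for (nm in map_names) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    if (file.exists(f)) maps[[nm]] <- read_mask(f, logical = FALSE) * 1
  }
  for (nm in names(maps)) {
    img <- RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz")))
    maps[[nm]] <- array(as.numeric(img), dim = dim(img)[1:3])
  }
  spacing <- RNifti::pixdim(RNifti::readNifti(
    file.path(dir, paste0(names(maps)[1], ".nii.gz"))))[1:3]
  provf <- file.path(dir, "provenance.nii.gz")
  prov <- if (file.exists(provf)) {
    img <- RNifti::readNifti(provf)
    array(as.integer(round(as.numeric(img))), dim = dim(img)[1:3])
  } else array(1L, dim(maps[[1]]))
  scalar_maps(maps, spacing, prov)
}

# short content hash of a scheme (order-sensitive), dependency-free
scheme_hash <- function(scheme) {
  v <- c(scheme$bvals, as.numeric(scheme$bvecs))
  s <- paste(sprintf("%.6g", v), collapse = ",")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}
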