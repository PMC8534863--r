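# Volume and mask containers plus ROI extraction.
#
# A pdff_volume is a 3D scalar field of fat-fraction percent with its voxel
# geometry; an roi_mask is a congruent binary mask labelled by muscle
# compartment (CE/ES/PS) and body side. All feature code reads voxels only
# through roi_values(), in a fixed scan order (x fastest, then y, then z —
# R's native column-major order), so results are bit-reproducible.

MUSCLES <- c("CE", "ES", "PS")
SIDES <- c("left", "right")

#' Construct a PDFF volume
#'
#' @param values 3D numeric array of PDFF in percent.
#' @param voxel_size voxel spacing in mm per axis (3 positive reals).
#' @param meta optional list of provenance metadata, passed through.
#' @return an object of class `pdff_volume`.
#' @export
pdff_volume <- function(values, voxel_size = c(1.5, 1.5, 1.5),
                        meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_pdff("`values` must be a 3D array", class = "pdff_shape_error")
  if (any(dim(values) < 1L))
    stop_pdff("all array extents must be >= 1", class = "pdff_shape_error")
  voxel_size <- as.double(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop_pdff("`voxel_size` must be 3 positive reals (mm)",
              class = "pdff_shape_error")
  structure(list(values = values, voxel_size = voxel_size, meta = meta),
            class = "pdff_volume")
}

#' Construct an ROI mask
#'
#' @param mask 3D logical (or 0/1) array, congruent with its volume.
#' @param muscle one of `"CE"`, `"ES"`, `"PS"`.
#' @param side `"left"` or `"right"`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, muscle, side) {
  muscle <- match.arg(muscle, MUSCLES)
  side <- match.arg(side, SIDES)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_pdff("`mask` must be a 3D array", class = "pdff_shape_error")
  m <- array(as.logical(mask), dim = dim(mask))
  structure(list(mask = m, muscle = muscle, side = side),
            class = "roi_mask")
}

#' @export
print.pdff_volume <- function(x, ...) {
  cat(sprintf("<pdff_volume %s @ %s mm, range [%.2f, %.2f]%%>\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask %s %s: %d voxels on %s grid>\n", x$muscle, x$side,
              sum(x$mask), paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Load a PDFF volume from NIfTI
#'
#' Values outside the physical range `[0, 100]` percent (possible in real
#' maps from noise) are clamped at load time; the number of clamped voxels
#' is recorded in `meta$n_clamped` and logged.
#'
#' @param path path to a 3D NIfTI-1 file (`.nii`/`.nii.gz`).
#' @return a [pdff_volume].
#' @export
load_volume <- function(path) {
  nii <- read_nifti(path)
  v <- nii$values
  n_clamped <- sum(v < 0 | v > 100)
  if (n_clamped > 0) {
    log_msg("info", sprintf("clamped %d out-of-range voxels in %s",
                            n_clamped, basename(path)))
    v[v < 0] <- 0
    v[v > 100] <- 100
  }
  pdff_volume(v, nii$voxel_size,
              meta = list(path = path, n_clamped = n_clamped))
}

#' Load an ROI mask from NIfTI
#'
#' The stored image is binarized at threshold 0.5 (tolerant of interpolated
#' masks). If `volume` is supplied the grids must match.
#'
#' @param path path to a 3D NIfTI-1 mask.
#' @param muscle,side labels for the ROI.
#' @param volume optional [pdff_volume] to validate the grid against.
#' @return an [roi_mask].
#' @export
load_mask <- function(path, muscle, side, volume = NULL) {
  nii <- read_nifti(path)
  m <- roi_mask(nii$values > 0.5, muscle, side)
  if (!is.null(volume) && !identical(dim(m$mask), dim(volume$values)))
    stop_pdff("mask grid %s does not match volume grid %s (%s)",
              paste(dim(m$mask), collapse = "x"),
              paste(dim(volume$values), collapse = "x"), path,
              class = "pdff_shape_error")
  m
}

#' Write a PDFF volume to NIfTI
#' @param volume a [pdff_volume].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_volume <- function(volume, path) {
  write_nifti(volume$values, path, volume$voxel_size, "float32")
}

#' Write an ROI mask to NIfTI
#' @param mask an [roi_mask].
#' @param path output `.nii`/`.nii.gz` path.
#' @param voxel_size voxel spacing in mm.
#' @export
write_mask <- function(mask, path, voxel_size = c(1.5, 1.5, 1.5)) {
  write_nifti(array(as.integer(mask$mask), dim = dim(mask$mask)),
              path, voxel_size, "uint8")
}

#' Extract the ROI voxel values
#'
#' Returns exactly the voxels where the mask is true, in fixed scan order
#' (x fastest, then y, then z).
#'
#' @param volume a [pdff_volume].
#' @param mask an [roi_mask] on the same grid.
#' @return numeric vector of PDFF percent values.
#' @export
roi_values <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$mask)))
    stop_pdff("mask grid %s does not match volume grid %s",
              paste(dim(mask$mask), collapse = "x"),
              paste(dim(volume$values), collapse = "x"),
              class = "pdff_shape_error")
  if (!any(mask$mask))
    stop_pdff("empty ROI: %s %s", mask$muscle, mask$side,
              class = "pdff_empty_roi_error")
  volume$values[mask$mask]
}

#' Geometric ROI volume in cubic millimetres
#'
#' @param mask an [roi_mask].
#' @param voxel_size voxel spacing in mm per axis.
#' @return voxel count times voxel volume, in mm^3.
#' @export
roi_volume_mm3 <- function(mask, voxel_size = c(1.5, 1.5, 1.5)) {
  sum(mask$mask) * prod(voxel_size)
}

#' Read / write a covariate table
#'
#' Covariate CSVs have columns `subject_id`, `sex` (`male`/`female`),
#' `age` (years), `bmi` (kg/m^2).
#'
#' @param path CSV path.
#' @return data.frame of covariates.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "bmi")
  if (!all(need %in% names(df)))
    stop_pdff("covariate table must have columns %s",
              paste(need, collapse = ", "), class = "pdff_io_error")
  if (anyDuplicated(df$subject_id))
    stop_pdff("duplicated subject_id in covariate table",
              class = "pdff_io_error")
  if (!all(df$sex %in% c("male", "female")))
    stop_pdff("sex must be 'male' or 'female'", class = "pdff_io_error")
  df
}

#' @rdname read_covariates
#' @param covariates data.frame to write.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}
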