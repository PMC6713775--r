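#' Attach physical voxel spacing to a 3D intensity array
#'
#' A volume grid is a plain 3D numeric array carrying its voxel spacing in
#' millimetres as an attribute. All geometric quantities downstream (volumes,
#' surfaces, diameters) are computed in physical units from this spacing.
#'
#' @param data 3D numeric array of intensities (HU for CT-like data).
#' @param spacing_mm numeric length-3, strictly positive voxel spacing in mm.
#' @return The array with class `volume_grid` and a `spacing` attribute.
#' @export
volume_grid <- function(data, spacing_mm = c(0.94, 0.94, 2.0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive values", call. = FALSE)
  structure(data, spacing = spacing_mm, class = c("volume_grid", class(data)))
}

#' Binary region-of-interest mask aligned to a volume grid
#'
#' @param data 3D logical (or 0/1) array.
#' @param spacing_mm voxel spacing in mm (same convention as [volume_grid()]).
#' @param artifact_slices integer indices of axial (third-dimension) slices
#'   flagged as containing metal artefacts. These slices are excluded from
#'   intensity/texture extraction but kept for geometric features.
#' @return Logical array with class `roi_mask`, `spacing` and
#'   `artifact_slices` attributes.
#' @export
roi_mask <- function(data, spacing_mm = c(0.94, 0.94, 2.0),
                     artifact_slices = integer(0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  m <- array(as.logical(data), dim = dim(data))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive values", call. = FALSE)
  structure(m, spacing = spacing_mm,
            artifact_slices = as.integer(artifact_slices),
            class = c("roi_mask", class(m)))
}

spacing_of <- function(x, default = c(0.94, 0.94, 2.0)) {
  s <- attr(x, "spacing")
  if (is.null(s)) default else s
}

#' Voxel volume in cubic centimetres
#' @param x a `volume_grid` or `roi_mask` (or anything with a spacing attribute)
#' @return scalar, cm^3 per voxel
#' @export
voxel_volume_cm3 <- function(x) prod(spacing_of(x)) / 1000

as_mask_array <- function(mask) array(as.logical(mask), dim = dim(mask))

#' Number of 6- or 26-connected components of a mask
#' @param mask 3D logical array
#' @param connectivity 6 or 26
#' @return integer component count
#' @export
n_components <- function(mask, connectivity = 6) {
  lab <- cpp_label(as.vector(as_mask_array(mask)), dim(mask), as.integer(connectivity))
  max(lab)
}

#' Write a volume or mask to NIfTI (or NRRD-style header-less fallback)
#'
#' @param x `volume_grid` or `roi_mask`
#' @param path output file path (`.nii` / `.nii.gz`)
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(array(as.numeric(x), dim = dim(x)))
  RNifti::pixdim(img) <- spacing_of(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a `volume_grid`
#' @param path file path
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume_grid(array(as.numeric(img), dim = dim(img)),
              spacing_mm = RNifti::pixdim(img)[1:3])
}
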