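# NIfTI input/output and grid resampling.
#
# NIfTI (.nii / .nii.gz) is the sole supported on-disk format; DICOM
# conversion is the user's responsibility.  At load every volume is
# reoriented to the package's canonical convention (array axis 1 increasing
# toward the patient's left, "LAS" in NIfTI orientation terms) so that the
# left/right label semantics are unambiguous downstream.

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI image, reorients it to the canonical left-positive axis
#' convention, and tags it with a modality. Negative PET values (possible
#' reconstruction artifacts) are clamped to 0, since SUV is non-negative by
#' definition.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @param modality `"CT_HU"` or `"PET_SUV"`.
#' @return An [image_volume].
#' @export
read_volume <- function(path, modality = c("CT_HU", "PET_SUV")) {
  modality <- match.arg(modality)
  img <- read_canonical(path)
  data <- strip_attrs(as.array(img))
  if (!all(is.finite(data)))
    stopf("'%s' contains non-finite voxel values", path)
  sp <- abs(RNifti::pixdim(img))[1:3]
  org <- nifti_origin(img)
  image_volume(data, spacing = sp, modality = modality, origin = org,
               clamp_negative = TRUE)
}

#' Read a NIfTI label volume
#'
#' @inheritParams read_volume
#' @return A [label_volume] with values in \{0, 1, 2\}.
#' @export
read_labels <- function(path) {
  img <- read_canonical(path)
  data <- strip_attrs(as.array(img))
  if (!all(data %in% c(0, 1, 2)))
    stopf("'%s' has labels outside {0, 1, 2}", path)
  label_volume(array(as.integer(data), dim = dim(data)),
               spacing = abs(RNifti::pixdim(img))[1:3],
               origin = nifti_origin(img))
}

strip_attrs <- function(x) array(as.vector(x), dim(x))

read_canonical <- function(path) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("cannot read '%s': %s", path,
                                            conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- RNifti::asNifti(array(as.array(img), dim = d[1:3]), reference = img)
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stopf("'%s' is not a 3D image (found %d dimensions)", path, length(d))
  xf <- RNifti::xform(img)
  if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0)
    RNifti::orientation(img) <- "LAS"
  img
}

nifti_origin <- function(img) {
  xf <- RNifti::xform(img)
  if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0) xf[1:3, 4] else c(0, 0, 0)
}

#' Write a volume to NIfTI
#'
#' Writes an image or label volume. The header records the volume's voxel
#' spacing; label volumes are stored as unsigned 8-bit integers. Files are
#' written in the canonical left-positive ("LAS") orientation, so a
#' write/read round trip is voxel-identical.
#'
#' @param vol An [image_volume] or [label_volume].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!(is_image_volume(vol) || is_label_volume(vol)))
    stopf("`vol` must be an image_volume or label_volume")
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("cannot write '%s': directory does not exist", path)
  data <- vol$data
  if (is_label_volume(vol)) storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vol$spacing
  img$sform_code <- 1L
  img$srow_x <- c(-vol$spacing[1], 0, 0, vol$origin[1])
  img$srow_y <- c(0, vol$spacing[2], 0, vol$origin[2])
  img$srow_z <- c(0, 0, vol$spacing[3], vol$origin[3])
  dtype <- if (is_label_volume(vol)) "uint8" else "double"
  tryCatch(RNifti::writeNifti(img, path, datatype = dtype),
           error = function(e) stopf("failed to write '%s': %s", path,
                                     conditionMessage(e)))
  invisible(path)
}

#' Resample a volume onto a new voxel grid
#'
#' Resamples onto an axis-aligned grid with the requested spacing, covering
#' the same physical extent (to within one voxel). Image volumes are
#' interpolated trilinearly; label volumes use nearest-neighbour
#' interpolation, the only label-safe choice. The edge-aligned mapping makes
#' resampling at the input spacing an exact identity.
#'
#' @param vol An [image_volume] or [label_volume].
#' @param target_spacing Numeric length-3, mm per voxel; all > 0.
#' @return A volume of the same class as `vol` on the new grid.
#' @export
resample_to_grid <- function(vol, target_spacing) {
  if (!is.numeric(target_spacing) || length(target_spacing) != 3L ||
      any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stopf("`target_spacing` must be 3 positive numbers (mm)")
  n_old <- dim(vol$data)
  n_new <- pmax(1L, as.integer(round(n_old * vol$spacing / target_spacing)))
  resample_to_shape(vol, target_spacing, n_new)
}

# Resample to an explicit target geometry (used internally to map labels
# back onto a native PET grid whose shape is already fixed).
resample_to_shape <- function(vol, target_spacing, target_shape) {
  ratio <- target_spacing / vol$spacing
  if (identical(as.integer(target_shape), as.integer(dim(vol$data))) &&
      all(abs(ratio - 1) < 1e-12)) {
    return(vol)  # exact identity
  }
  A <- diag(ratio, 3)
  b <- 0.5 * ratio - 0.5   # voxel-edge-aligned: in = (out + .5) * ratio - .5
  method <- if (is_label_volume(vol)) 1L else 0L
  out <- .affine_sample(as.double(vol$data), dim(vol$data),
                        as.integer(target_shape), A, b, method,
                        TRUE, 0)
  if (is_label_volume(vol)) {
    label_volume(array(as.integer(round(out)), dim = target_shape),
                 spacing = target_spacing, origin = vol$origin)
  } else {
    image_volume(out, spacing = target_spacing, modality = vol$modality,
                 origin = vol$origin, clamp_negative = TRUE)
  }
}
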