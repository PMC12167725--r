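# Canonical in-memory volume containers.
#
# All volumes use a fixed anatomical axis convention: axis 1 of the array
# increases toward the patient's LEFT, so "left kidney" (label 1) always
# means anatomical left.  Axes 2 and 3 are the remaining in-plane and
# longitudinal directions.  Voxel centres sit at (i - 0.5) * spacing mm
# (1-based index i) from the volume edge.

#' Construct an image volume
#'
#' A 3D scalar grid with physical voxel spacing, world origin, and a
#' modality tag. PET volumes carry standardized uptake values (SUV, always
#' non-negative); CT volumes carry Hounsfield units (HU).
#'
#' @param data 3D numeric array of finite values.
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param modality `"CT_HU"` or `"PET_SUV"`.
#' @param origin Numeric length-3, world position (mm) of the first voxel.
#' @param clamp_negative If `TRUE` and modality is `"PET_SUV"`, negative
#'   values (e.g. reconstruction artifacts) are clamped to 0 instead of
#'   raising an error.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, modality = c("CT_HU", "PET_SUV"),
                         origin = c(0, 0, 0), clamp_negative = FALSE) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stopf("grid shape must be >= 1 along every axis")
  if (!all(is.finite(data))) stopf("image volume contains non-finite voxels")
  if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stopf("`spacing` must be 3 positive numbers (mm)")
  if (modality == "PET_SUV" && any(data < 0)) {
    if (clamp_negative) data[data < 0] <- 0
    else stopf("PET_SUV volume has negative values; SUV must be >= 0")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), modality = modality),
            class = "image_volume")
}

#' Construct a label volume
#'
#' A 3D integer grid on the same geometry as its paired image volume, with
#' label semantics 0 = background, 1 = left kidney, 2 = right kidney.
#'
#' @param data 3D array of integers in \{0, 1, 2\}.
#' @inheritParams image_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array")
  if (!all(data %in% c(0L, 1L, 2L)))
    stopf("label volume values must be in {0, 1, 2}")
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stopf("`spacing` must be 3 positive numbers (mm)")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

is_image_volume <- function(x) inherits(x, "image_volume")
is_label_volume <- function(x) inherits(x, "label_volume")

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- tabulate(x$data + 1L, nbins = 3L)
  cat(sprintf(
    "<label_volume> %s voxels, spacing %s mm, background/left/right = %d/%d/%d\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing), collapse = "x"), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
dim.label_volume <- function(x) dim(x$data)

#' @export
as.array.image_volume <- function(x, ...) x$data

#' @export
as.array.label_volume <- function(x, ...) x$data

# Geometry equality used wherever an image and a label volume are paired.
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

assert_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stopf("%s must share geometry (shape, spacing, origin)", what)
  invisible(TRUE)
}

#' Mirror a volume left-right
#'
#' Flips the volume along the left-right axis (array axis 1). For label
#' volumes the left/right kidney labels are swapped so that the labels keep
#' their anatomical meaning in the mirrored patient.
#'
#' @param vol An `image_volume` or `label_volume`.
#' @return A volume of the same class.
#' @export
mirror_volume <- function(vol) {
  n <- dim(vol$data)[1]
  flipped <- vol$data[n:1, , , drop = FALSE]
  if (is_label_volume(vol)) {
    swapped <- flipped
    swapped[flipped == 1L] <- 2L
    swapped[flipped == 2L] <- 1L
    label_volume(swapped, vol$spacing, vol$origin)
  } else {
    image_volume(flipped, vol$spacing, vol$modality, vol$origin)
  }
}
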