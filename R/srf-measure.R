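# Inference-side measurement: scores -> labels, largest-connected-component
# cleanup, kidney volumes, and the LRF% statistic.
#
# LRF% (left renal function percentage) is the summed SUV of all voxels in
# the left-kidney segmentation divided by the summed SUV of both kidney
# segmentations, times 100.

#' Convert 3-class scores to labels
#'
#' Per-voxel argmax over the class axis; ties break toward the lowest class
#' index, so an all-tied voxel is background.
#'
#' @param scores Numeric array `(nx, ny, nz, 3)` of finite scores.
#' @param spacing,origin Geometry for the resulting volume.
#' @return A [label_volume].
#' @export
scores_to_labels <- function(scores, spacing = c(2.73, 2.73, 2.79),
                             origin = c(0, 0, 0)) {
  d <- dim(scores)
  if (length(d) != 4L || d[4] != 3L) stopf("`scores` must be (nx, ny, nz, 3)")
  if (!all(is.finite(scores))) stopf("scores contain non-finite values")
  N <- prod(d[1:3])
  lab <- max.col(matrix(scores, N, 3), ties.method = "first") - 1L
  label_volume(array(lab, d[1:3]), spacing, origin)
}

#' Keep only the largest 26-connected component of one kidney class
#'
#' Among voxels of class `target`, only the largest 26-connected component
#' (face, edge and corner adjacency) keeps its label; every other voxel of
#' that class becomes background. Other classes are untouched, and an
#' absent class returns the volume unchanged. An exact size tie keeps the
#' component whose smallest linear voxel index is smallest, which is
#' deterministic.
#'
#' @param labels A [label_volume].
#' @param target 1 (left kidney) or 2 (right kidney).
#' @return A [label_volume].
#' @export
keep_largest_component <- function(labels, target) {
  stopifnot(is_label_volume(labels))
  if (!target %in% c(1L, 2L)) stopf("`target` must be 1 or 2")
  cc <- .label_components26(labels$data, dim(labels$data), as.integer(target))
  if (length(cc$sizes) <= 1L) return(labels)
  keep <- which.max(cc$sizes)   # first maximum = smallest min linear index
  out <- labels$data
  out[cc$comp != 0L & cc$comp != keep] <- 0L
  label_volume(out, labels$spacing, labels$origin)
}

#' Segmented volume in millilitres
#'
#' Count of `target` voxels times the voxel volume
#' `prod(spacing)` mm^3 / 1000.
#'
#' @param labels A [label_volume].
#' @param target Label whose volume to measure.
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(labels, target) {
  stopifnot(is_label_volume(labels))
  sum(labels$data == target) * prod(labels$spacing) / 1000
}

#' Compute split renal function from a PET volume and a segmentation
#'
#' Sums the SUV over the left- and right-kidney voxels and reports
#' `LRF% = 100 * left / (left + right)` together with per-kidney volumes.
#' A segmentation with no renal uptake at all (both sums zero) is a
#' measurement error, never a silent number.
#'
#' @param pet A PET [image_volume] (values >= 0).
#' @param labels A [label_volume] on the same geometry.
#' @return An object of class `srf_result` with fields `left_suv_sum`,
#'   `right_suv_sum`, `left_volume_ml`, `right_volume_ml`, `lrf_percent`,
#'   and a `warnings` character vector.
#' @export
compute_srf <- function(pet, labels) {
  stopifnot(is_image_volume(pet), is_label_volume(labels))
  if (pet$modality != "PET_SUV") stopf("`pet` must be a PET_SUV volume")
  assert_same_geometry(pet, labels, "pet and labels")
  lsum <- sum(pet$data[labels$data == 1L])
  rsum <- sum(pet$data[labels$data == 2L])
  if (lsum + rsum == 0) stopf("no renal uptake segmented")
  structure(list(left_suv_sum = lsum, right_suv_sum = rsum,
                 left_volume_ml = mask_volume_ml(labels, 1L),
                 right_volume_ml = mask_volume_ml(labels, 2L),
                 lrf_percent = 100 * lsum / (lsum + rsum),
                 warnings = character(0)),
            class = "srf_result")
}

#' @export
print.srf_result <- function(x, ...) {
  cat(sprintf("Split renal function\n  LRF%%: %.1f\n", x$lrf_percent))
  cat(sprintf("  left : SUV sum %.1f, volume %.1f ml\n",
              x$left_suv_sum, x$left_volume_ml))
  cat(sprintf("  right: SUV sum %.1f, volume %.1f ml\n",
              x$right_suv_sum, x$right_volume_ml))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

tile_starts <- function(n, edge, stride) {
  if (edge >= n) return(1L)
  s <- seq(1L, n - edge + 1L, by = stride)
  if (tail(s, 1) + edge - 1L < n) s <- c(s, n - edge + 1L)
  as.integer(s)
}

# Full-volume scoring by overlapping-patch inference: 50% stride, mean
# fusion of scores in overlaps.  Volumes smaller than the tile are padded
# with ambient values and cropped back.
predict_scores <- function(model, ct_arr, pet_arr, tile_edge = NULL) {
  cfg <- model$net_cfg
  if (isTRUE(model$symmetrized)) {
    base <- model; base$symmetrized <- FALSE
    s1 <- predict_scores(base, ct_arr, pet_arr, tile_edge)
    n <- dim(ct_arr)[1]
    s2 <- predict_scores(base, ct_arr[n:1, , , drop = FALSE],
                         pet_arr[n:1, , , drop = FALSE], tile_edge)
    s2 <- s2[n:1, , , c(1L, 3L, 2L), drop = FALSE]  # unflip, swap L/R scores
    return((s1 + s2) / 2)
  }
  if (is.null(tile_edge))
    tile_edge <- if (!is.null(model$train_cfg)) model$train_cfg$patch_edge else 32L
  d <- dim(ct_arr)
  pad <- pmax(0L, tile_edge - d)
  if (any(pad > 0L)) {
    dp <- pmax(d, tile_edge)
    ctp <- array(-100, dp); petp <- array(0, dp)
    ctp[1:d[1], 1:d[2], 1:d[3]] <- ct_arr
    petp[1:d[1], 1:d[2], 1:d[3]] <- pet_arr
    sc <- predict_scores(model, ctp, petp, tile_edge)
    return(sc[1:d[1], 1:d[2], 1:d[3], , drop = FALSE])
  }
  stride <- max(1L, tile_edge %/% 2L)
  acc <- array(0, c(d, 3L))
  cnt <- array(0, d)
  for (i in tile_starts(d[1], tile_edge, stride))
    for (j in tile_starts(d[2], tile_edge, stride))
      for (k in tile_starts(d[3], tile_edge, stride)) {
        xi <- i:(i + tile_edge - 1L)
        yj <- j:(j + tile_edge - 1L)
        zk <- k:(k + tile_edge - 1L)
        x <- make_input(ct_arr[xi, yj, zk, drop = FALSE],
                        pet_arr[xi, yj, zk, drop = FALSE], cfg)
        sc <- unet_forward(model, x)$scores[[1]]
        acc[xi, yj, zk, ] <- acc[xi, yj, zk, , drop = FALSE] + sc
        cnt[xi, yj, zk] <- cnt[xi, yj, zk] + 1
      }
  acc / as.vector(cnt)
}

#' Segment a PET/CT study and measure split renal function
#'
#' End-to-end pipeline: both volumes are resampled to the model grid, the
#' volume is scored by overlapping-patch inference (mean fusion), scores
#' become labels by argmax, only the largest 26-connected component of each
#' kidney class is kept, the cleaned labels are mapped back to the native
#' PET grid by nearest neighbour, and LRF% is computed from the native-grid
#' SUV values (so no interpolated SUV enters the sums). A kept component
#' smaller than 10 ml is flagged in the result's `warnings` as a likely
#' spurious segmentation (e.g. an avid lymph node mistaken for a kidney).
#'
#' @param ct CT [image_volume], co-registered with `pet`.
#' @param pet PET [image_volume].
#' @param model A trained `srf_model` (see [train_model]).
#' @return List with `labels` (a [label_volume] on the native PET grid) and
#'   `result` (an `srf_result`).
#' @export
segment_and_measure <- function(ct, pet, model) {
  stopifnot(inherits(model, "srf_model"),
            is_image_volume(ct), is_image_volume(pet))
  assert_same_geometry(ct, pet, "ct and pet")
  ct_m <- resample_to_grid(ct, model$spacing)
  pet_m <- resample_to_grid(pet, model$spacing)
  scores <- predict_scores(model, ct_m$data, pet_m$data)
  labels <- scores_to_labels(scores, spacing = model$spacing,
                             origin = pet_m$origin)
  labels <- keep_largest_component(labels, 1L)
  labels <- keep_largest_component(labels, 2L)
  native <- resample_to_shape(labels, pet$spacing, dim(pet$data))
  native$origin <- pet$origin
  result <- compute_srf(pet, native)
  for (side in c(1L, 2L)) {
    vol <- mask_volume_ml(native, side)
    if (vol > 0 && vol < 10)
      result$warnings <- c(result$warnings,
                           sprintf("%s kidney component is only %.1f ml; possibly spurious",
                                   c("left", "right")[side], vol))
  }
  list(labels = native, result = result)
}

#' Enforce left-right mirror consistency of a model
#'
#' Wraps a model so that its scores are the average of the plain forward
#' pass and the forward pass on the left-right mirrored input with the
#' kidney score channels swapped back. The wrapped model is exactly
#' equivariant under mirroring: segmenting a mirrored study yields the
#' mirrored segmentation, so LRF% of the mirrored study is exactly the
#' complement `100 - LRF%`.
#'
#' @param model An `srf_model`.
#' @return The model with symmetrized inference.
#' @export
symmetrize_model <- function(model) {
  stopifnot(inherits(model, "srf_model"))
  model$symmetrized <- TRUE
  model
}
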