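# Seeded, paired augmentation of (CT, PET, label) training patches.
#
# One affine transform (scale . rotate . shear . translate, drawn once) is
# applied identically to all three patches: trilinear resampling for CT and
# PET, nearest neighbour for labels.  Intensity perturbations (HU shift and
# scale, smoothing, additive Gaussian noise) touch the CT channel only:
# perturbing SUV by default would corrupt the very quantity the LRF%
# statistic is built from.  PET intensity noise is available behind a flag,
# off by default.

#' Augmentation parameters
#'
#' All magnitudes are intervals from which one value is drawn per patch;
#' each transform is applied independently with probability `apply_prob`.
#' Defaults are conventional for abdominal CT segmentation.
#'
#' @param scale_range Unitless isotropic scale interval.
#' @param translate_range Translation interval in mm (per axis).
#' @param rotate_range Rotation interval in degrees (per axis).
#' @param shear_range Unitless shear-factor interval (per axis pair).
#' @param hu_shift_range Additive HU interval (CT only).
#' @param hu_scale_range Multiplicative HU interval (CT only).
#' @param smooth_sigma_range Gaussian smoothing sigma interval in mm (CT only).
#' @param noise_sd_range Additive Gaussian noise SD interval in HU (CT only).
#' @param apply_prob Per-transform application probability in \[0, 1\].
#' @param pet_noise If `TRUE`, additive noise is also drawn for the PET
#'   channel (same SD interval, SUV units). Off by default.
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(scale_range = c(0.9, 1.1),
                           translate_range = c(-10, 10),
                           rotate_range = c(-10, 10),
                           shear_range = c(-0.05, 0.05),
                           hu_shift_range = c(-50, 50),
                           hu_scale_range = c(0.9, 1.1),
                           smooth_sigma_range = c(0, 1.5),
                           noise_sd_range = c(0, 20),
                           apply_prob = 0.5,
                           pet_noise = FALSE) {
  for (nm in c("scale_range", "translate_range", "rotate_range", "shear_range",
               "hu_shift_range", "hu_scale_range", "smooth_sigma_range",
               "noise_sd_range"))
    check_range(get(nm), nm)
  check_scalar_num(apply_prob, "apply_prob", lower = 0, upper = 1)
  structure(list(scale_range = scale_range, translate_range = translate_range,
                 rotate_range = rotate_range, shear_range = shear_range,
                 hu_shift_range = hu_shift_range, hu_scale_range = hu_scale_range,
                 smooth_sigma_range = smooth_sigma_range,
                 noise_sd_range = noise_sd_range, apply_prob = apply_prob,
                 pet_noise = isTRUE(pet_noise)),
            class = "augment_params")
}

rot3 <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Augment a (CT, PET, label) patch triple
#'
#' Draws one spatial transform and applies it identically to all three
#' patches, then perturbs the CT intensities. Fully deterministic given
#' `(inputs, params, seed)`. Out-of-field voxels created by the affine are
#' filled with ambient values: CT -100 HU, PET 0 SUV, labels 0.
#'
#' @param ct,pet 3D numeric arrays sharing one shape.
#' @param labels 3D integer array (values in \{0, 1, 2\}) of the same shape.
#' @param params An [augment_params].
#' @param spacing Voxel spacing in mm (rotation and translation are metric).
#' @param seed Optional integer; if `NULL` the current RNG stream is used
#'   (as inside the training loop).
#' @return List with augmented `ct`, `pet`, `labels` arrays, plus the drawn
#'   affine as attribute `"affine"`.
#' @export
augment_triple <- function(ct, pet, labels, params,
                           spacing = c(2.73, 2.73, 2.79), seed = NULL) {
  stopifnot(inherits(params, "augment_params"))
  if (!identical(dim(ct), dim(pet)) || !identical(dim(ct), dim(labels)))
    stopf("ct, pet and labels patches must share one shape")
  if (!is.null(seed)) return(with_seed(seed, augment_triple(ct, pet, labels,
                                                            params, spacing)))
  p <- params
  gate <- runif(8) < p$apply_prob
  # parameters are always drawn, in fixed order, so the stream is stable
  sc <- runif(1, p$scale_range[1], p$scale_range[2])
  rot <- runif(3, p$rotate_range[1], p$rotate_range[2])
  sh <- runif(3, p$shear_range[1], p$shear_range[2])
  tr <- runif(3, p$translate_range[1], p$translate_range[2])
  hu_shift <- runif(1, p$hu_shift_range[1], p$hu_shift_range[2])
  hu_scale <- runif(1, p$hu_scale_range[1], p$hu_scale_range[2])
  sm_sigma <- runif(1, p$smooth_sigma_range[1], p$smooth_sigma_range[2])
  noise_sd <- runif(1, p$noise_sd_range[1], p$noise_sd_range[2])
  if (!gate[1]) sc <- 1
  if (!gate[2]) rot <- c(0, 0, 0)
  if (!gate[3]) sh <- c(0, 0, 0)
  if (!gate[4]) tr <- c(0, 0, 0)

  S <- diag(rep(sc, 3))
  Sh <- diag(3); Sh[1, 2] <- sh[1]; Sh[1, 3] <- sh[2]; Sh[2, 3] <- sh[3]
  L <- S %*% rot3(rot) %*% Sh

  dims <- dim(ct)
  if (!all(L == diag(3)) || !all(tr == 0)) {
    # pull-back: for each output voxel find the source position in mm,
    # about the patch centre
    cen <- dims * spacing / 2
    Linv <- solve(L)
    A <- diag(1 / spacing) %*% Linv %*% diag(spacing)
    b <- (Linv %*% (0.5 * spacing - cen - tr) + cen) / spacing - 0.5
    ct <- .affine_sample(as.double(ct), dims, dims, A, as.double(b), 0L,
                         FALSE, -100)
    pet <- .affine_sample(as.double(pet), dims, dims, A, as.double(b), 0L,
                          FALSE, 0)
    lab <- .affine_sample(as.double(labels), dims, dims, A, as.double(b), 1L,
                          FALSE, 0)
    labels <- array(as.integer(round(lab)), dims)
    pet[pet < 0] <- 0
  }
  if (gate[5]) ct <- ct + hu_shift
  if (gate[6]) ct <- ct * hu_scale
  if (gate[7] && sm_sigma > 0)
    ct <- .gaussian_blur3(as.double(ct), dims, sm_sigma / spacing)
  if (gate[8] && noise_sd > 0) {
    ct <- ct + array(rnorm(prod(dims), 0, noise_sd), dims)
    if (p$pet_noise) {
      pet <- pet + array(rnorm(prod(dims), 0, noise_sd / 20), dims)
      pet[pet < 0] <- 0
    }
  }
  out <- list(ct = ct, pet = pet, labels = labels)
  attr(out, "affine") <- list(L = L, t = tr)
  out
}
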