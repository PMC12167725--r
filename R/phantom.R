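# Synthetic renal phantom simulator.
#
# Generates paired CT/PET volumes with ground-truth kidney labels and an
# analytically known true LRF%.  The phantom paints piecewise-constant SUV
# and HU fields (background, abdominal organs, kidneys as an ellipsoidal
# cortex shell around a low-uptake pelvis core, a high-uptake bladder, and
# optional para-aortic distractor lesions), then applies a Gaussian
# point-spread blur and additive noise to the PET channel.  The true LRF%
# is defined on the pre-blur, pre-noise field restricted to the truth
# masks, giving an exact recovery target; blur and noise effects then
# become measurable biases.

#' Specify one kidney
#'
#' An ellipsoidal kidney with a high-uptake cortex shell and a low-uptake
#' pelvis core (inner ellipsoid at 55% of the semi-axes).
#'
#' @param present Logical; `FALSE` simulates a missing (e.g. surgically
#'   removed) kidney.
#' @param center Numeric length-3, ellipsoid centre in mm.
#' @param semi_axes Numeric length-3, ellipsoid semi-axes in mm; all > 0.
#' @param cortex_suv Mean SUV of the cortex shell; must exceed `pelvis_suv`.
#' @param pelvis_suv SUV of the inner low-uptake core; >= 0.
#' @param uptake_scale Unitless multiplier on both SUV fields; >= 0. Values
#'   well below 1 model low-uptake (poorly functioning) kidneys.
#' @return An object of class `kidney_spec`.
#' @export
kidney_spec <- function(present = TRUE, center, semi_axes = c(28, 20, 40),
                        cortex_suv = 25, pelvis_suv = 5, uptake_scale = 1) {
  if (!is.logical(present) || length(present) != 1L)
    stopf("`present` must be TRUE or FALSE")
  if (length(center) != 3L || any(!is.finite(center)))
    stopf("`center` must be 3 finite numbers (mm)")
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stopf("`semi_axes` must be 3 positive numbers (mm)")
  check_scalar_num(cortex_suv, "cortex_suv", lower = 0)
  check_scalar_num(pelvis_suv, "pelvis_suv", lower = 0)
  if (cortex_suv <= pelvis_suv) stopf("`cortex_suv` must exceed `pelvis_suv`")
  check_scalar_num(uptake_scale, "uptake_scale", lower = 0)
  structure(list(present = present, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), cortex_suv = cortex_suv,
                 pelvis_suv = pelvis_suv, uptake_scale = uptake_scale),
            class = "kidney_spec")
}

#' Specify a synthetic abdomen
#'
#' Full parameterization of one phantom case. Defaults describe a
#' 64x64x64 desk-scale abdomen at the scanner voxel spacing of
#' 2.73 x 2.73 x 2.79 mm (about a 17 x 17 x 18 cm field of view), with the
#' qualitative contrast of PSMA-ligand PET: intensely avid renal cortex and
#' bladder, moderate-uptake abdominal organs, faint background.
#'
#' @param shape Integer length-3 grid dimensions.
#' @param spacing Voxel spacing in mm (default the scanner grid
#'   2.73 x 2.73 x 2.79).
#' @param left,right [kidney_spec] for each kidney. Axis 1 increases toward
#'   the patient's left, so the left kidney must lie in the high-index half.
#' @param background_suv,background_hu Ambient soft-tissue values.
#' @param kidney_hu CT value of kidney parenchyma.
#' @param bladder List `(center, radius, suv, hu)` of the urinary bladder.
#' @param organs List of moderate-uptake spheres, each
#'   `list(center, radius, suv, hu)`.
#' @param lesions List of para-aortic distractor spheres
#'   `list(center, radius, suv)` emulating avid lymph-node metastases, the
#'   known failure mode for solitary-kidney cases.
#' @param psf_fwhm Gaussian point-spread FWHM in mm applied to PET; >= 0.
#' @param pet_noise_sd,ct_noise_sd Additive zero-mean Gaussian noise SD
#'   (SUV and HU respectively).
#' @param seed Integer seed; all phantom randomness derives from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(2.73, 2.73, 2.79),
                         left = kidney_spec(center = c(130, 100, 95)),
                         right = kidney_spec(center = c(45, 100, 95)),
                         background_suv = 1, background_hu = 40,
                         kidney_hu = 35,
                         bladder = list(center = c(87, 87, 24), radius = 15,
                                        suv = 60, hu = 10),
                         organs = list(
                           # liver: large, high uptake (hepatic clearance of
                           # the tracer), abutting the right kidney's upper
                           # pole as in real anatomy
                           list(center = c(50, 75, 138), radius = 28,
                                suv = 12, hu = 60),
                           # spleen: smaller, moderate uptake, by the left
                           # kidney's upper pole
                           list(center = c(136, 80, 138), radius = 13,
                                suv = 6, hu = 45)),
                         lesions = list(),
                         psf_fwhm = 5, pet_noise_sd = 1, ct_noise_sd = 15,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("`shape` must be 3 positive integers")
  if (length(spacing) != 3L || any(spacing <= 0)) stopf("`spacing` must be positive")
  stopifnot(inherits(left, "kidney_spec"), inherits(right, "kidney_spec"))
  check_scalar_num(background_suv, "background_suv", lower = 0)
  check_scalar_num(psf_fwhm, "psf_fwhm", lower = 0)
  check_scalar_num(pet_noise_sd, "pet_noise_sd", lower = 0)
  check_scalar_num(ct_noise_sd, "ct_noise_sd", lower = 0)
  mid <- shape[1] * spacing[1] / 2
  if (left$present && left$center[1] <= mid)
    stopf("left kidney centre must lie on the patient-left (high-index) half")
  if (right$present && right$center[1] >= mid)
    stopf("right kidney centre must lie on the patient-right (low-index) half")
  for (org in organs)
    if (org$suv < 0) stopf("organ SUV must be >= 0")
  for (les in lesions)
    if (les$suv < 0) stopf("lesion SUV must be >= 0")
  if (bladder$suv < 0) stopf("bladder SUV must be >= 0")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 left = left, right = right,
                 background_suv = background_suv, background_hu = background_hu,
                 kidney_hu = kidney_hu, bladder = bladder, organs = organs,
                 lesions = lesions, psf_fwhm = psf_fwhm,
                 pet_noise_sd = pet_noise_sd, ct_noise_sd = ct_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Voxel-centre coordinate grids in mm (centre of voxel i at (i - 0.5) * s).
voxel_centers <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[3]) - 0.5) * spacing[3])
}

ellipsoid_mask <- function(shape, spacing, center, semi_axes) {
  g <- voxel_centers(shape, spacing)
  dx2 <- ((g$x - center[1]) / semi_axes[1])^2
  dy2 <- ((g$y - center[2]) / semi_axes[2])^2
  dz2 <- ((g$z - center[3]) / semi_axes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

sphere_mask <- function(shape, spacing, center, radius) {
  ellipsoid_mask(shape, spacing, center, rep(radius, 3))
}

#' Generate one phantom case
#'
#' Paints the noiseless SUV and HU fields, rasterizes the truth mask from
#' the kidney ellipsoids, computes the analytic true LRF% on the pre-blur,
#' pre-noise SUV field, then blurs (PET only), adds noise, and clamps PET
#' at zero.
#'
#' @param spec A [phantom_spec].
#' @return An object of class `phantom_case`: a list with elements `ct`,
#'   `pet` ([image_volume]s), `truth` ([label_volume]), `true_lrf_percent`,
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; sp <- spec$spacing
  pet <- array(spec$background_suv, dim = shape)
  ct <- array(spec$background_hu, dim = shape)

  for (org in spec$organs) {
    m <- sphere_mask(shape, sp, org$center, org$radius)
    pet[m] <- org$suv
    ct[m] <- org$hu
  }

  truth <- array(0L, dim = shape)
  paint_kidney <- function(ks, lab) {
    if (!ks$present) return(invisible(NULL))
    outer_m <- ellipsoid_mask(shape, sp, ks$center, ks$semi_axes)
    inner_m <- ellipsoid_mask(shape, sp, ks$center, 0.55 * ks$semi_axes)
    pet[outer_m] <<- ks$cortex_suv * ks$uptake_scale
    pet[inner_m] <<- ks$pelvis_suv * ks$uptake_scale
    ct[outer_m] <<- spec$kidney_hu
    truth[outer_m] <<- lab
    invisible(NULL)
  }
  left_m <- if (spec$left$present)
    ellipsoid_mask(shape, sp, spec$left$center, spec$left$semi_axes) else
      array(FALSE, shape)
  right_m <- if (spec$right$present)
    ellipsoid_mask(shape, sp, spec$right$center, spec$right$semi_axes) else
      array(FALSE, shape)
  if (any(left_m & right_m)) stopf("kidney ellipsoids overlap")
  bl_m <- sphere_mask(shape, sp, spec$bladder$center, spec$bladder$radius)
  if (any(bl_m & (left_m | right_m)))
    stopf("bladder overlaps a kidney ellipsoid")
  paint_kidney(spec$left, 1L)
  paint_kidney(spec$right, 2L)

  pet[bl_m] <- spec$bladder$suv
  ct[bl_m] <- spec$bladder$hu
  for (les in spec$lesions) {
    m <- sphere_mask(shape, sp, les$center, les$radius)
    if (any(m & (left_m | right_m))) stopf("lesion overlaps a kidney ellipsoid")
    pet[m] <- les$suv
    if (!is.null(les$hu)) ct[m] <- les$hu
  }

  # analytic LRF% on the pre-blur, pre-noise field
  lsum <- sum(pet[truth == 1L])
  rsum <- sum(pet[truth == 2L])
  if (lsum + rsum == 0) stopf("phantom has no kidney uptake; cannot define LRF%%")
  true_lrf <- 100 * lsum / (lsum + rsum)

  with_seed(spec$seed, {
    if (spec$psf_fwhm > 0) {
      sigma_vox <- (spec$psf_fwhm / (2 * sqrt(2 * log(2)))) / sp
      pet <- .gaussian_blur3(pet, shape, sigma_vox)
    }
    if (spec$pet_noise_sd > 0)
      pet <- pet + array(rnorm(prod(shape), 0, spec$pet_noise_sd), shape)
    if (spec$ct_noise_sd > 0)
      ct <- ct + array(rnorm(prod(shape), 0, spec$ct_noise_sd), shape)
  })
  pet[pet < 0] <- 0

  structure(list(
    ct = image_volume(ct, sp, "CT_HU"),
    pet = image_volume(pet, sp, "PET_SUV"),
    truth = label_volume(truth, sp),
    true_lrf_percent = true_lrf,
    spec = spec), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s grid, true LRF%% = %.2f\n",
              paste(dim(x$ct$data), collapse = "x"), x$true_lrf_percent))
  invisible(x)
}

#' Generate a cohort of phantom cases
#'
#' Draws `n` cases with per-case variation of kidney size (+/-25% on the
#' semi-axes), uptake (+/-50%), and position jitter, in a mix of anatomical
#' variants. The default mix follows the composition of the training
#' cohort the segmenter is designed for: mostly two normal kidneys plus a
#' minority of solitary kidneys, hypoplastic kidneys, and cases with
#' symmetric or asymmetric low uptake.
#'
#' @param n Number of cases; >= 1.
#' @param seed Integer seed; the cohort is a pure function of
#'   `(n, seed, variant_mix)`.
#' @param variant_mix Named fractions over
#'   `c("normal", "solitary", "hypoplastic", "low_symmetric",
#'   "low_asymmetric")`; must sum to 1. Counts are the rounded fractions of
#'   `n` (largest-remainder rounding, so counts always sum to `n`).
#' @param shape,spacing Grid passed to each [phantom_spec].
#' @param lesion_prob Probability that a case receives one para-aortic
#'   distractor lesion.
#' @return List of [generate_phantom] cases; each carries its `spec` (and a
#'   `variant` attribute) for reproducibility.
#' @export
generate_cohort <- function(n, seed,
                            variant_mix = c(normal = 120 / 136,
                                            solitary = 6 / 136,
                                            hypoplastic = 5 / 136,
                                            low_symmetric = 1 / 136,
                                            low_asymmetric = 4 / 136),
                            shape = c(64, 64, 64),
                            spacing = c(2.73, 2.73, 2.79),
                            lesion_prob = 0) {
  if (n < 1) stopf("`n` must be >= 1")
  variants <- c("normal", "solitary", "hypoplastic", "low_symmetric",
                "low_asymmetric")
  if (is.null(names(variant_mix)) || !all(names(variant_mix) %in% variants))
    stopf("`variant_mix` must be named with the known variants")
  mix <- setNames(numeric(5), variants)
  mix[names(variant_mix)] <- variant_mix
  if (abs(sum(mix) - 1) > 1e-9)
    stopf("`variant_mix` fractions must sum to 1 (got %.6f)", sum(mix))
  counts <- largest_remainder_round(mix * n)

  with_seed(seed, {
    variant_of <- sample(rep(variants, counts))
    fov <- shape * spacing
    # anatomy scales with the field of view so that small desk grids stay
    # collision-free; the reference FOV is the default 64^3 grid
    sc <- min(1, fov[1] / (64 * 2.73))
    base_left <- c(0.74, 0.57, 0.53) * fov
    base_right <- c(0.26, 0.57, 0.53) * fov
    lapply(seq_len(n), function(i) {
      v <- variant_of[i]
      make_kidney <- function(center0) {
        size <- runif(1, 0.75, 1.25)
        uptake <- runif(1, 0.5, 1.5)
        jitter <- runif(3, -6 * sc, 6 * sc)
        kidney_spec(center = center0 + jitter,
                    semi_axes = c(28, 20, 40) * size * sc,
                    uptake_scale = uptake)
      }
      left <- make_kidney(base_left)
      right <- make_kidney(base_right)
      affected <- sample(c("left", "right"), 1)
      if (v == "solitary") {
        if (affected == "left") left$present <- FALSE else right$present <- FALSE
      } else if (v == "hypoplastic") {
        if (affected == "left") left$semi_axes <- left$semi_axes * 0.5
        else right$semi_axes <- right$semi_axes * 0.5
      } else if (v == "low_symmetric") {
        left$uptake_scale <- left$uptake_scale * 0.3
        right$uptake_scale <- right$uptake_scale * 0.3
      } else if (v == "low_asymmetric") {
        if (affected == "left") left$uptake_scale <- left$uptake_scale * 0.3
        else right$uptake_scale <- right$uptake_scale * 0.3
      }
      lesions <- list()
      if (runif(1) < lesion_prob) {
        # para-aortic: midline, between the kidneys
        lesions <- list(list(center = c(0.5, 0.45, 0.62) * fov +
                               runif(3, -5 * sc, 5 * sc),
                             radius = runif(1, 5, 9) * sc,
                             suv = runif(1, 10, 30), hu = 45))
      }
      spec <- phantom_spec(shape = shape, spacing = spacing,
                           left = left, right = right, lesions = lesions,
                           bladder = list(center = c(0.5, 0.5, 0.135) * fov,
                                          radius = 15 * sc, suv = 60, hu = 10),
                           organs = list(
                             list(center = c(0.29, 0.43, 0.77) * fov,
                                  radius = 28 * sc, suv = 12, hu = 60),
                             list(center = c(0.78, 0.46, 0.77) * fov,
                                  radius = 13 * sc, suv = 6, hu = 45)),
                           seed = sample.int(2147483646L, 1))
      case <- generate_phantom(spec)
      attr(case, "variant") <- v
      case$case_id <- sprintf("case_%03d", i)
      case
    })
  })
}

largest_remainder_round <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  need <- round(sum(x)) - sum(fl)
  if (need > 0) {
    ord <- order(rem, decreasing = TRUE)
    fl[ord[seq_len(need)]] <- fl[ord[seq_len(need)]] + 1
  }
  as.integer(fl)
}

#' Simulate a human reader's segmentation
#'
#' Stands in for additional human readers: perturbs a ground-truth
#' segmentation by shifting each kidney's boundary independently by a
#' random amount drawn uniformly in `[-magnitude, magnitude]` voxels
#' (negative = erosion, positive = dilation), using the full 26-connected
#' structuring element. The integer part of the drawn amount is applied as
#' whole morphological steps; the fractional part perturbs a matching
#' random fraction of the next boundary shell, emulating the sub-voxel
#' boundary disagreement of careful human readers.
#'
#' @param truth A [label_volume].
#' @param magnitude Maximum boundary shift in voxels; >= 0. Zero returns
#'   the truth unchanged.
#' @param seed Integer seed for the per-kidney draws.
#' @return A [label_volume]; labels remain in \{0, 1, 2\}.
#' @export
simulate_reader <- function(truth, magnitude, seed = 1L) {
  stopifnot(is_label_volume(truth))
  check_scalar_num(magnitude, "magnitude", lower = 0)
  if (magnitude == 0) return(truth)
  out <- truth$data
  d <- dim(out)
  with_seed(seed, {
    for (lab in c(1L, 2L)) {
      u <- runif(1, -magnitude, magnitude)
      op <- if (u > 0) 1L else 0L
      whole <- floor(abs(u))
      frac <- abs(u) - whole
      if (!any(out == lab)) next
      mask <- array(as.integer(out == lab), d)
      for (i in seq_len(whole)) mask <- .morph26(mask, d, op)
      if (frac > 0) {
        full <- .morph26(mask, d, op)
        shell <- which(full != mask)
        pick <- shell[runif(length(shell)) < frac]
        mask[pick] <- full[pick]
      }
      out[out == lab] <- 0L
      # dilation claims only background voxels, never the other kidney
      claim <- mask == 1L & out == 0L
      out[claim] <- lab
    }
  })
  label_volume(out, truth$spacing, truth$origin)
}

#' Write a cohort to disk
#'
#' Writes each case as a directory of NIfTI volumes (`ct.nii.gz`,
#' `pet.nii.gz`, `truth.nii.gz`) plus a JSON manifest of specs and true
#' LRF% values.
#'
#' @param cohort List of phantom cases from [generate_cohort].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort, function(case) {
    id <- case$case_id
    cdir <- file.path(dir, id)
    dir.create(cdir, showWarnings = FALSE)
    write_volume(case$ct, file.path(cdir, "ct.nii.gz"))
    write_volume(case$pet, file.path(cdir, "pet.nii.gz"))
    write_volume(case$truth, file.path(cdir, "truth.nii.gz"))
    list(case_id = id, variant = attr(case, "variant"),
         true_lrf_percent = case$true_lrf_percent,
         spec = spec_to_list(case$spec))
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a cohort written by [save_cohort]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return List of cases (`ct`, `pet`, `truth`, `true_lrf_percent`,
#'   `case_id`).
#' @export
load_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stopf("no manifest.json in '%s'", dir)
  manifest <- jsonlite::read_json(mf_path)
  lapply(manifest, function(entry) {
    cdir <- file.path(dir, entry$case_id)
    structure(list(
      ct = read_volume(file.path(cdir, "ct.nii.gz"), "CT_HU"),
      pet = read_volume(file.path(cdir, "pet.nii.gz"), "PET_SUV"),
      truth = read_labels(file.path(cdir, "truth.nii.gz")),
      true_lrf_percent = as.numeric(entry$true_lrf_percent),
      case_id = entry$case_id), class = "phantom_case")
  })
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$left <- unclass(out$left)
  out$right <- unclass(out$right)
  out
}
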