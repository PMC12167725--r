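# Scores -> labels, connected-component cleanup, volumes, LRF%.

test_that("argmax of one-hot scores recovers the labels, ties go background", {
  lab <- array(sample(0:2, 5^3, TRUE), c(5, 5, 5))
  scores <- array(0, c(5, 5, 5, 3))
  for (k in 0:2) scores[, , , k + 1][lab == k] <- 3
  out <- scores_to_labels(scores)
  expect_identical(out$data, array(as.integer(lab), dim(lab)))
  tied <- array(1.5, c(3, 3, 3, 3))
  expect_true(all(scores_to_labels(tied)$data == 0L))
  set.seed(8)
  rnd <- scores_to_labels(array(rnorm(4^3 * 3), c(4, 4, 4, 3)))
  expect_true(all(rnd$data %in% 0:2))
  bad <- array(0, c(2, 2, 2, 3)); bad[1] <- NA
  expect_error(scores_to_labels(bad), "non-finite")
})

test_that("a single connected blob passes through unchanged", {
  lab <- array(0L, c(8, 8, 8)); lab[3:5, 3:5, 3:5] <- 1L
  lv <- label_volume(lab, c(1, 1, 1))
  expect_identical(keep_largest_component(lv, 1L)$data, lab)
  expect_identical(keep_largest_component(lv, 2L)$data, lab)  # absent class
})

test_that("smaller components of the target class are removed", {
  lab <- array(0L, c(12, 12, 12))
  lab[2:6, 2:6, 2:6] <- 1L            # 125 voxels
  lab[10:11, 10:11, 10]  <- 1L        # 4 voxels, separated
  lab[8, 2, 2] <- 2L                  # other class untouched
  out <- keep_largest_component(label_volume(lab, c(1, 1, 1)), 1L)
  expect_identical(sum(out$data == 1L), 125L)
  expect_identical(out$data[10, 10, 10], 0L)
  expect_identical(out$data[8, 2, 2], 2L)
})

test_that("corner-contact voxels form one 26-connected component", {
  lab <- array(0L, c(4, 4, 4))
  lab[1, 1, 1] <- 1L
  lab[2, 2, 2] <- 1L   # shares only a corner
  lab[4, 4, 4] <- 1L   # a separate single voxel (smaller "component")
  out <- keep_largest_component(label_volume(lab, c(1, 1, 1)), 1L)
  expect_identical(sum(out$data == 1L), 2L)
  expect_identical(out$data[1, 1, 1], 1L)
  expect_identical(out$data[2, 2, 2], 1L)
})

test_that("equal-size components keep the one with the smallest linear index", {
  lab <- array(0L, c(6, 6, 6))
  lab[5:6, 5:6, 5] <- 1L   # 4 voxels, later in linear order
  lab[1:2, 1:2, 1] <- 1L   # 4 voxels, first
  out <- keep_largest_component(label_volume(lab, c(1, 1, 1)), 1L)
  expect_identical(out$data[1, 1, 1], 1L)
  expect_identical(out$data[5, 5, 5], 0L)
})

test_that("largest-component filtering is idempotent and matches the oracle", {
  set.seed(10)
  for (i in 1:10) {
    lab <- array(sample(0:2, 10^3, TRUE, prob = c(0.85, 0.08, 0.07)),
                 c(10, 10, 10))
    lv <- label_volume(lab, c(1, 1, 1))
    once <- keep_largest_component(lv, 1L)
    expect_identical(keep_largest_component(once, 1L)$data, once$data)
    expect_identical(once$data, oracle_keep_largest(lv$data, 1L))
  }
})

test_that("mask volumes follow the spacing product", {
  lab <- array(0L, c(10, 10, 10)); lab[1:10, 1:10, 1:10] <- 1L
  lv <- label_volume(lab, c(2.73, 2.73, 2.79))
  expect_equal(mask_volume_ml(lv, 1L), 1000 * 2.73 * 2.73 * 2.79 / 1000,
               tolerance = 1e-9)
  expect_identical(mask_volume_ml(lv, 2L), 0)
  lv2 <- label_volume(lab, 2 * c(2.73, 2.73, 2.79))
  expect_equal(mask_volume_ml(lv2, 1L), 8 * mask_volume_ml(lv, 1L),
               tolerance = 1e-9)
})

test_that("LRF% matches hand sums and handles one-sided cases", {
  pet <- array(0, c(4, 4, 4))
  lab <- array(0L, c(4, 4, 4))
  pet[1, 1, 1] <- 10; pet[2, 1, 1] <- 20; lab[1:2, 1, 1] <- 1L
  pet[4, 4, 4] <- 10; lab[4, 4, 4] <- 2L
  res <- compute_srf(image_volume(pet, c(1, 1, 1), "PET_SUV"),
                     label_volume(lab, c(1, 1, 1)))
  expect_equal(res$lrf_percent, 75, tolerance = 1e-12)
  expect_equal(res$left_suv_sum, 30)
  # empty right mask -> 100%
  lab2 <- lab; lab2[lab2 == 2L] <- 0L
  expect_equal(compute_srf(image_volume(pet, c(1, 1, 1), "PET_SUV"),
                           label_volume(lab2, c(1, 1, 1)))$lrf_percent, 100)
  # nothing segmented at all -> measurement error
  expect_error(compute_srf(image_volume(pet, c(1, 1, 1), "PET_SUV"),
                           label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "no renal uptake")
})

test_that("LRF% is exactly complemented under mirroring", {
  for (seed in 1:5) {
    case <- generate_phantom(tiny_phantom_spec(seed = seed))
    lrf <- compute_srf(case$pet, case$truth)$lrf_percent
    lrf_m <- compute_srf(mirror_volume(case$pet),
                         mirror_volume(case$truth))$lrf_percent
    expect_equal(lrf_m, 100 - lrf, tolerance = 1e-9)
  }
})

test_that("compute_srf is invariant to voxel order (pure reduction)", {
  set.seed(11)
  pet <- array(abs(rnorm(6^3, 5)), c(6, 6, 6))
  lab <- array(sample(0:2, 6^3, TRUE), c(6, 6, 6))
  perm <- sample(6^3)
  a <- compute_srf(image_volume(pet, c(1, 1, 1), "PET_SUV"),
                   label_volume(lab, c(1, 1, 1)))
  b <- compute_srf(image_volume(array(pet[perm], dim(pet)), c(1, 1, 1),
                                "PET_SUV"),
                   label_volume(array(lab[perm], dim(lab)), c(1, 1, 1)))
  expect_equal(a$lrf_percent, b$lrf_percent, tolerance = 1e-12)
  expect_equal(a$left_suv_sum, b$left_suv_sum, tolerance = 1e-12)
})

test_that("tiled inference equals a direct pass when one tile covers the volume", {
  m <- tiny_trained_model()
  case <- generate_phantom(tiny_phantom_spec(seed = 30))
  x <- srfpet:::make_input(case$ct$data, case$pet$data, m$net_cfg)
  direct <- srfpet:::unet_forward(m, x)$scores[[1]]
  tiled <- srfpet:::predict_scores(m, case$ct$data, case$pet$data)
  expect_equal(tiled, direct, tolerance = 1e-12)
})

test_that("segment_and_measure recovers phantom LRF% with a trained model", {
  m <- tiny_trained_model()
  case <- generate_phantom(tiny_phantom_spec(seed = 31))
  seg <- segment_and_measure(case$ct, case$pet, m)
  expect_s3_class(seg$labels, "label_volume")
  expect_true(all(dim(seg$labels$data) == dim(case$pet$data)))
  expect_gt(dice(seg$labels$data == 1, case$truth$data == 1), 0.6)
  expect_lt(abs(seg$result$lrf_percent - case$true_lrf_percent), 5)
})

test_that("an all-background model propagates the measurement error", {
  cfg <- network_config(levels = 2, base_channels = 2)
  m <- build_unet(cfg, seed = 2)
  # force a huge background bias so argmax is background everywhere
  m$params[["head1.b"]] <- c(100, 0, 0)
  m$train_cfg <- train_config(patch_edge = 16L)
  case <- generate_phantom(tiny_phantom_spec(seed = 32))
  expect_error(segment_and_measure(case$ct, case$pet, m), "no renal uptake")
})
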