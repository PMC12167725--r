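# Phantom generator: analytic LRF%, cohort composition, simulated readers.

test_that("mirror-symmetric kidneys with equal uptake give true LRF% of 50", {
  spec <- phantom_spec()
  # defaults place the kidneys symmetrically about the midplane
  case <- generate_phantom(spec)
  expect_equal(case$true_lrf_percent, 50, tolerance = 0.5)
  sym <- tiny_phantom_spec()
  expect_equal(generate_phantom(sym)$true_lrf_percent, 50, tolerance = 1e-9)
})

test_that("3x left uptake with identical geometry gives true LRF% of 75", {
  spec <- tiny_phantom_spec()
  spec$left$uptake_scale <- 3
  spec$right$uptake_scale <- 1
  expect_equal(generate_phantom(spec)$true_lrf_percent, 75, tolerance = 1e-9)
})

test_that("a solitary left kidney gives true LRF% of 100", {
  spec <- tiny_phantom_spec()
  spec$right$present <- FALSE
  expect_equal(generate_phantom(spec)$true_lrf_percent, 100)
  spec2 <- tiny_phantom_spec()
  spec2$left$present <- FALSE
  expect_equal(generate_phantom(spec2)$true_lrf_percent, 0)
})

test_that("true LRF% equals the measurement formula on the noiseless field", {
  for (seed in 1:5) {
    spec <- tiny_phantom_spec(seed = seed, psf_fwhm = 0, pet_noise_sd = 0,
                              ct_noise_sd = 0)
    spec$left$uptake_scale <- runif(1, 0.5, 1.5)
    case <- generate_phantom(spec)
    res <- compute_srf(case$pet, case$truth)
    expect_equal(res$lrf_percent, case$true_lrf_percent, tolerance = 1e-9)
  }
})

test_that("phantom generation is a pure function of its spec", {
  a <- generate_phantom(tiny_phantom_spec(seed = 42))
  b <- generate_phantom(tiny_phantom_spec(seed = 42))
  expect_identical(a$pet$data, b$pet$data)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$truth$data, b$truth$data)
})

test_that("overlapping kidney ellipsoids are a spec error", {
  spec <- tiny_phantom_spec()
  spec$left$center <- c(46, 44, 44)
  spec$right$center <- c(41, 44, 44)
  expect_error(generate_phantom(spec), "overlap")
})

test_that("cohort variant counts equal rounded fractions of n", {
  cohort <- generate_cohort(10, seed = 3,
                            variant_mix = c(solitary = 0.5, normal = 0.5),
                            shape = c(32, 32, 32))
  n_solitary <- sum(vapply(cohort, function(case)
    sum(!case$spec$left$present, !case$spec$right$present), numeric(1)) == 1)
  expect_identical(length(cohort), 10L)
  expect_identical(n_solitary, 5L)
})

test_that("an all-normal cohort keeps true LRF% in a band around 50", {
  cohort <- generate_cohort(16, seed = 11, variant_mix = c(normal = 1),
                            shape = c(32, 32, 32))
  lrf <- vapply(cohort, function(case) case$true_lrf_percent, numeric(1))
  expect_true(all(lrf > 15 & lrf < 85))
  expect_equal(median(lrf), 50, tolerance = 12)
})

test_that("cohorts are voxel-identical for identical (n, seed, mix)", {
  a <- generate_cohort(4, seed = 5, shape = c(32, 32, 32))
  b <- generate_cohort(4, seed = 5, shape = c(32, 32, 32))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$pet$data, b[[i]]$pet$data)
    expect_identical(a[[i]]$truth$data, b[[i]]$truth$data)
  }
  d <- generate_cohort(4, seed = 6, shape = c(32, 32, 32))
  expect_false(identical(a[[1]]$pet$data, d[[1]]$pet$data))
})

test_that("variant mixes must sum to one", {
  expect_error(generate_cohort(4, seed = 1,
                               variant_mix = c(normal = 0.6, solitary = 0.3)),
               "sum to 1")
})

test_that("simulated reader at magnitude zero is the identity", {
  case <- generate_phantom(tiny_phantom_spec())
  r <- simulate_reader(case$truth, 0, seed = 1)
  expect_identical(r$data, case$truth$data)
})

test_that("26-connected dilation of a 3-cube yields a 5-cube", {
  lab <- array(0L, c(9, 9, 9))
  lab[4:6, 4:6, 4:6] <- 1L
  dil <- srfpet:::.morph26(lab, dim(lab), 1L)
  expect_identical(sum(dil), 125L)
  expect_identical(array(dil > 0, dim(lab)),
                   oracle_dilate26(lab))
  ero <- srfpet:::.morph26(lab, dim(lab), 0L)
  expect_identical(sum(ero), 1L)  # 3-cube erodes to its centre voxel
})

test_that("reader DSC degrades with perturbation magnitude", {
  case <- generate_phantom(tiny_phantom_spec(seed = 8))
  mean_dsc <- vapply(c(0, 1, 3), function(m) {
    mean(vapply(1:16, function(s) {
      r <- simulate_reader(case$truth, m, seed = 100 * m + s)
      (dice(r$data == 1, case$truth$data == 1) +
         dice(r$data == 2, case$truth$data == 2)) / 2
    }, numeric(1)))
  }, numeric(1))
  expect_identical(mean_dsc[1], 1)
  expect_true(all(diff(mean_dsc) <= 0.02))  # non-increasing up to draw noise
  expect_true(all(simulate_reader(case$truth, 2, seed = 3)$data %in% 0:2))
})

test_that("cohorts survive a save/load round trip", {
  tmp <- withr::local_tempdir()
  cohort <- generate_cohort(2, seed = 9, shape = c(32, 32, 32))
  save_cohort(cohort, tmp)
  expect_true(file.exists(file.path(tmp, "manifest.json")))
  back <- load_cohort(tmp)
  expect_identical(length(back), 2L)
  expect_equal(back[[1]]$pet$data, cohort[[1]]$pet$data, tolerance = 1e-6)
  expect_identical(back[[1]]$truth$data, cohort[[1]]$truth$data)
  expect_equal(back[[2]]$true_lrf_percent, cohort[[2]]$true_lrf_percent,
               tolerance = 1e-9)
})

test_that("noisy blurred measurement stays near the analytic truth", {
  # truth-mask measurement under the default PSF blur (5 mm) and noise
  # (SD 1 SUV): within 2 ppt of the analytic truth in at least 95% of
  # 100 seeded phantoms
  devs <- vapply(1:100, function(seed) {
    case <- generate_phantom(tiny_phantom_spec(seed = seed))
    abs(compute_srf(case$pet, case$truth)$lrf_percent - case$true_lrf_percent)
  }, numeric(1))
  expect_gte(mean(devs < 2), 0.95)
})
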