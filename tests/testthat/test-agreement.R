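# Dice, Bland-Altman, Spearman, pairwise records and the report layout.

test_that("dice handles identity, disjoint, partial and empty masks", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
  expect_identical(dice(a, a), 1)
  b <- array(FALSE, c(4, 4, 4)); b[3:4, 3:4, 3:4] <- TRUE
  expect_identical(dice(a, b), 0)
  # |A| = 8, |B| = 8, |A n B| = 4 -> 0.5
  c1 <- array(FALSE, c(4, 4, 4)); c1[1:8] <- TRUE
  c2 <- array(FALSE, c(4, 4, 4)); c2[5:12] <- TRUE
  expect_equal(dice(c1, c2), 0.5, tolerance = 1e-12)
  empty <- array(FALSE, c(4, 4, 4))
  expect_identical(dice(empty, empty), 1)   # both-empty convention
  expect_identical(dice(a, empty), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, array(FALSE, c(4, 4, 5))), "share geometry")
})

test_that("Bland-Altman matches closed forms with the n-1 denominator", {
  z <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_identical(z$bias, 0)
  expect_identical(c(z$loa_low, z$loa_high), c(0, 0))
  cst <- bland_altman(c(3, 4, 5), c(1, 2, 3))
  expect_equal(cst$bias, 2)
  expect_equal(c(cst$loa_low, cst$loa_high), c(2, 2))
  alt <- bland_altman(c(1, -1, 1, -1), c(0, 0, 0, 0))
  expect_equal(alt$bias, 0)
  s <- sqrt(4 / 3)
  expect_equal(alt$loa_high, 1.96 * s, tolerance = 1e-9)
  expect_equal(alt$loa_low, -1.96 * s, tolerance = 1e-9)
  expect_true(alt$loa_low <= alt$bias && alt$bias <= alt$loa_high)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Spearman matches the rank formula and its invariances", {
  expect_equal(spearman(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6, tolerance = 1e-12)
  expect_equal(spearman(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               oracle_spearman_noties(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               tolerance = 1e-12)
  x <- c(3, 1, 4, 1.5, 9)
  y <- c(2, 0.1, 8, 1, 40)
  expect_equal(spearman(x, y), 1)
  expect_equal(spearman(x, -y), -1)
  expect_equal(spearman(exp(x), y^3), spearman(x, y), tolerance = 1e-12)
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  expect_error(spearman(1:2, 1:2), "n >= 3")
})

test_that("pairwise records are antisymmetric and self-comparison degenerate", {
  case <- generate_phantom(tiny_phantom_spec(seed = 15))
  reader <- simulate_reader(case$truth, 1, seed = 2)
  self <- compare_pair(case$truth, case$truth, case$pet)
  expect_identical(self$dsc_left, 1)
  expect_identical(self$dsc_right, 1)
  expect_identical(self$diff_vol_left_ml, 0)
  expect_identical(self$diff_lrf_ppt, 0)
  ab <- compare_pair(case$truth, reader, case$pet, "c", "truth", "r2")
  ba <- compare_pair(reader, case$truth, case$pet, "c", "r2", "truth")
  expect_equal(ab$diff_lrf_ppt, -ba$diff_lrf_ppt, tolerance = 1e-12)
  expect_equal(ab$diff_vol_left_ml, -ba$diff_vol_left_ml, tolerance = 1e-12)
  expect_equal(ab$dsc_left, ba$dsc_left, tolerance = 1e-12)
  expect_lt(ab$dsc_left, 1)
  # a voxel-scale boundary shift on a small phantom moves cortex shell SUV;
  # the LRF% perturbation stays bounded but is not negligible on this grid
  expect_lt(abs(ab$diff_lrf_ppt), 15)
})

test_that("evaluate_sources produces k(k-1) ordered records per case", {
  cases <- lapply(1:2, function(i) {
    case <- generate_phantom(tiny_phantom_spec(seed = i))
    list(case_id = sprintf("case%d", i), pet = case$pet,
         sources = list(truth = case$truth,
                        r2 = simulate_reader(case$truth, 1, seed = i),
                        r3 = simulate_reader(case$truth, 1, seed = i + 50)))
  })
  agr <- evaluate_sources(cases)
  expect_identical(nrow(agr$records), 2L * 3L * 2L)  # cases x k(k-1)
  expect_identical(nrow(agr$measurements), 6L)
  summ <- summarize_agreement(agr)
  expect_identical(nrow(summ$pairs), 3L)  # unordered pairs in report
})

test_that("identical sources summarize to a degenerate report", {
  cases <- lapply(1:3, function(i) {
    case <- generate_phantom(tiny_phantom_spec(seed = i + 20))
    list(case_id = sprintf("case%d", i), pet = case$pet,
         sources = list(a = case$truth, b = case$truth, c = case$truth))
  })
  summ <- summarize_agreement(evaluate_sources(cases))
  expect_true(all(summ$pairs$dsc_median == 1))
  expect_true(all(summ$pairs$diff_vol_median == 0))
  expect_true(all(summ$pairs$diff_lrf_median == 0))
  for (ba in summ$bland_altman) {
    expect_identical(ba$bias, 0)
    expect_identical(ba$loa_high, 0)
  }
})

test_that("summary medians are plain order statistics", {
  rec <- do.call(rbind, lapply(1:3, function(i)
    data.frame(case_id = paste0("c", i), source_a = "a", source_b = "b",
               dsc_left = c(0.9, 0.95, 1.0)[i],
               dsc_right = c(0.9, 0.95, 1.0)[i],
               diff_vol_left_ml = 0, diff_vol_right_ml = 0,
               diff_lrf_ppt = c(-1, 0, 2)[i])))
  summ <- summarize_agreement(rec)
  expect_equal(summ$pairs$dsc_median, 0.95)
  expect_equal(summ$pairs$dsc_min, 0.9)
  expect_equal(summ$pairs$dsc_max, 1.0)
  expect_equal(summ$pairs$diff_lrf_median, 0)
})

test_that("simulated readers keep high rank agreement on LRF%", {
  # full-size grid: sub-voxel boundary shifts are then proportionally
  # small against kidney volume, as for careful human readers
  cases <- lapply(1:10, function(i) {
    case <- generate_cohort(1, seed = i + 40, variant_mix = c(normal = 1))[[1]]
    list(case_id = sprintf("case%d", i), pet = case$pet,
         sources = list(truth = case$truth,
                        r2 = simulate_reader(case$truth, 0.3, seed = i),
                        r3 = simulate_reader(case$truth, 0.3, seed = i + 90)))
  })
  summ <- summarize_agreement(evaluate_sources(cases))
  off_diag <- summ$spearman_lrf[upper.tri(summ$spearman_lrf)]
  expect_true(all(off_diag >= 0.9))
})
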