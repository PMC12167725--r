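# U-Net architecture arithmetic, the weighted loss, deep supervision, and
# gradient correctness.

test_that("desk configuration maps 32^3 input to full-res plus one aux head", {
  cfg <- network_config(levels = 2, base_channels = 8)
  m <- build_unet(cfg, seed = 1)
  x <- array(rnorm(32^3 * 2), c(32, 32, 32, 2))
  out <- srfpet:::unet_forward(m, x)
  expect_length(out$scores, 2)
  expect_identical(dim(out$scores[[1]]), c(32L, 32L, 32L, 3L))
  expect_identical(dim(out$scores[[2]]), c(16L, 16L, 16L, 3L))
  expect_true(all(vapply(m$params, function(p) all(is.finite(p)), logical(1))))
})

test_that("patch edges not divisible by 2^(levels-1) are rejected by name", {
  cfg <- network_config(levels = 3, base_channels = 4)
  m <- build_unet(cfg, seed = 1)
  x <- array(0, c(10, 10, 10, 2))
  expect_error(srfpet:::unet_forward(m, x), "divisible by 4")
})

test_that("two builds from the same seed have identical parameters", {
  cfg <- network_config(levels = 2, base_channels = 4)
  a <- build_unet(cfg, seed = 7)
  b <- build_unet(cfg, seed = 7)
  expect_identical(a$params, b$params)
  d <- build_unet(cfg, seed = 8)
  expect_false(identical(a$params, d$params))
})

test_that("uniform scores on all-background labels give loss ln 3", {
  scores <- array(0.7, c(4, 4, 4, 3))  # equal for all classes
  labels <- array(0L, c(4, 4, 4))
  expect_equal(weighted_ce(scores, labels), log(3), tolerance = 1e-9)
})

test_that("near-one-hot correct scores drive the loss to zero monotonically", {
  labels <- array(sample(0:2, 4^3, TRUE), c(4, 4, 4))
  onehot <- array(0, c(4, 4, 4, 3))
  for (k in 0:2) onehot[, , , k + 1][labels == k] <- 1
  losses <- vapply(c(2, 5, 10, 20), function(conf)
    weighted_ce(onehot * conf, labels), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[4], 1e-8)
})

test_that("the weighted mean combines kidney and background voxels as (5a+b)/6", {
  # 2-voxel patch: one kidney voxel with per-voxel ce = a, one background
  # voxel with ce = b
  scores <- array(0, c(2, 1, 1, 3))
  scores[1, 1, 1, ] <- c(0.2, 1.4, -0.5)   # voxel 1: true class 1 (left)
  scores[2, 1, 1, ] <- c(1.1, 0.3, 0.9)    # voxel 2: true class 0
  labels <- array(c(1L, 0L), c(2, 1, 1))
  p1 <- exp(scores[1, 1, 1, ]) / sum(exp(scores[1, 1, 1, ]))
  p2 <- exp(scores[2, 1, 1, ]) / sum(exp(scores[2, 1, 1, ]))
  a <- -log(p1[2]); b <- -log(p2[1])
  expect_equal(weighted_ce(scores, labels), (5 * a + b) / 6, tolerance = 1e-9)
})

test_that("softmax probabilities sum to one at every voxel", {
  set.seed(3)
  scores <- array(rnorm(5^3 * 3, 0, 10), c(5, 5, 5, 3))
  p <- srfpet:::softmax_scores(scores)
  expect_equal(apply(p, 1:3, sum), array(1, c(5, 5, 5)), tolerance = 1e-6)
})

test_that("the loss is symmetric under a left-right class relabel", {
  set.seed(4)
  scores <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  labels <- array(sample(0:2, 6^3, TRUE), c(6, 6, 6))
  swapped_scores <- scores[, , , c(1, 3, 2)]
  swapped_labels <- labels
  swapped_labels[labels == 1L] <- 2L
  swapped_labels[labels == 2L] <- 1L
  expect_equal(weighted_ce(scores, labels),
               weighted_ce(swapped_scores, swapped_labels), tolerance = 1e-12)
})

test_that("deep supervision reduces to the plain loss for trivial weightings", {
  set.seed(5)
  s1 <- array(rnorm(8^3 * 3), c(8, 8, 8, 3))
  s2 <- array(rnorm(4^3 * 3), c(4, 4, 4, 3))
  labels <- array(sample(0:2, 8^3, TRUE), c(8, 8, 8))
  expect_equal(deep_supervision_loss(list(s1), labels, scale_weights = 1),
               weighted_ce(s1, labels), tolerance = 1e-12)
  expect_equal(deep_supervision_loss(list(s1, s2), labels,
                                     scale_weights = c(1, 0)),
               weighted_ce(s1, labels), tolerance = 1e-12)
  # uniform scores at every scale, all-background labels: ln 3 regardless
  u1 <- array(2, c(8, 8, 8, 3)); u2 <- array(-1, c(4, 4, 4, 3))
  bg <- array(0L, c(8, 8, 8))
  expect_equal(deep_supervision_loss(list(u1, u2), bg,
                                     scale_weights = c(0.3, 0.7)),
               log(3), tolerance = 1e-9)
})

test_that("analytic softmax cross-entropy gradient matches finite differences", {
  # 1-voxel toy patch, double precision: p - onehot, weighted
  set.seed(6)
  scores <- array(rnorm(3), c(1, 1, 1, 3))
  labels <- array(1L, c(1, 1, 1))
  g <- srfpet:::weighted_ce_grad(scores, labels)
  h <- 1e-6
  for (k in 1:3) {
    sp <- scores; sp[1, 1, 1, k] <- sp[1, 1, 1, k] + h
    sm <- scores; sm[1, 1, 1, k] <- sm[1, 1, 1, k] - h
    fd <- (weighted_ce(sp, labels) - weighted_ce(sm, labels)) / (2 * h)
    expect_equal(g[1, 1, 1, k], fd, tolerance = 1e-4)
  }
})

test_that("network gradients agree with finite differences", {
  set.seed(42)
  cfg <- network_config(levels = 2, base_channels = 2)
  m <- build_unet(cfg, seed = 3)
  n <- 8
  ct <- array(rnorm(n^3, 0, 50), rep(n, 3))
  pet <- array(abs(rnorm(n^3, 5, 3)), rep(n, 3))
  lab <- array(sample(0:2, n^3, TRUE), rep(n, 3))
  x <- srfpet:::make_input(ct, pet, cfg)
  lossfn <- function(mm)
    deep_supervision_loss(srfpet:::unet_forward(mm, x)$scores, lab)
  fwd <- srfpet:::unet_forward(m, x, want_cache = TRUE)
  g <- srfpet:::unet_backward(m, fwd$cache,
                              srfpet:::ds_loss_grad(fwd$scores, lab))
  h <- 1e-3
  # representative parameters from head, decoder, encoder and upconv;
  # tolerance reflects single-precision conv arithmetic
  for (nm in c("head1.W", "dec1.conv2.W", "enc1.conv1.W", "up1.W",
               "enc2.conv2.b")) {
    for (i in c(1L, length(m$params[[nm]]))) {
      m2 <- m; m2$params[[nm]][i] <- m$params[[nm]][i] + h
      m3 <- m; m3$params[[nm]][i] <- m$params[[nm]][i] - h
      fd <- (lossfn(m2) - lossfn(m3)) / (2 * h)
      expect_equal(g[[nm]][i], fd, tolerance = 0.01,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("weighted_ce validates labels and geometry", {
  scores <- array(0, c(2, 2, 2, 3))
  bad <- array(3L, c(2, 2, 2))
  expect_error(weighted_ce(scores, bad), "0, 1, 2")
  expect_error(weighted_ce(scores, array(0L, c(2, 2, 1))), "aligned")
  expect_error(deep_supervision_loss(list(scores), array(0L, c(2, 2, 2)),
                                     scale_weights = c(1, 1)),
               "one entry per scale")
})
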