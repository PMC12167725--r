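# Configurable 3D U-Net over (CT, SUV) channels with deep supervision and
# class-weighted categorical cross-entropy.
#
# The encoder/decoder follows the classic volumetric U-Net design: two
# 3x3x3 same-padding convolutions per resolution level with channel counts
# doubling per level, instance normalization and rectified linear units,
# 2x2x2 max-pooling down and 2x2x2 transposed convolution up, skip
# connections by channel concatenation.  A 1x1x1 head produces 3-class
# scores (background, left kidney, right kidney) at the finest scale and,
# when deep supervision is on, at every coarser decoder scale.  Scores are
# unnormalized; softmax lives inside the loss and the inference decision
# rule, which is numerically the stable place for it.

#' Network configuration
#'
#' @param levels Number of resolution scales; >= 2. The full-size profile
#'   uses 4, the desk profile 2.
#' @param base_channels Feature maps at the finest level (full 16, desk 8).
#' @param deep_supervision Attach a scoring head at every scale.
#' @param rescale_input Apply the fixed affine input rescale HU/100,
#'   SUV/10 inside the forward pass; crude channel balancing that keeps the
#'   two raw modalities on comparable numeric scales.
#' @param relu_slope Negative-side slope of the rectifier. A small leak
#'   keeps every feature map trainable on short schedules; a hard
#'   rectifier (slope 0) can silence whole feature maps over entire
#'   structures, freezing the information they carried.
#' @return Object of class `network_config`. Input channels are fixed at 2
#'   (CT, PET) and output classes at 3.
#' @export
network_config <- function(levels = 4L, base_channels = 16L,
                           deep_supervision = TRUE, rescale_input = TRUE,
                           relu_slope = 0.1) {
  levels <- as.integer(levels); base_channels <- as.integer(base_channels)
  if (levels < 2L) stopf("`levels` must be >= 2")
  if (base_channels < 1L) stopf("`base_channels` must be >= 1")
  check_scalar_num(relu_slope, "relu_slope", lower = 0, upper = 1)
  structure(list(levels = levels, base_channels = base_channels,
                 in_channels = 2L, out_classes = 3L,
                 deep_supervision = isTRUE(deep_supervision),
                 rescale_input = isTRUE(rescale_input),
                 relu_slope = relu_slope, padding = "same"),
            class = "network_config")
}

#' Class weights for the segmentation loss
#'
#' The kidney classes are upweighted relative to background to counter the
#' extreme class imbalance of torso volumes (kidney weight 5, background 1).
#'
#' @param background,left_kidney,right_kidney Positive weights.
#' @return Numeric length-3 vector of class `class_weights`.
#' @export
class_weights <- function(background = 1, left_kidney = 5, right_kidney = 5) {
  w <- c(background = background, left_kidney = left_kidney,
         right_kidney = right_kidney)
  if (any(w <= 0)) stopf("all class weights must be > 0")
  structure(w, class = "class_weights")
}

unet_channels <- function(cfg) cfg$base_channels * 2^(0:(cfg$levels - 1))

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

#' Build a (untrained) U-Net segmentation model
#'
#' Initializes all parameters (He-scaled Gaussian weights, zero biases,
#' unit-gain instance norms). Deterministic given `seed`.
#'
#' @param config A [network_config].
#' @param seed Integer seed for the parameter draw.
#' @param spacing Voxel grid (mm) the model operates on; inputs are
#'   resampled to this spacing at inference. Default is the scanner grid
#'   2.73 x 2.73 x 2.79 mm.
#' @return Object of class `srf_model`.
#' @export
build_unet <- function(config = network_config(), seed = 1L,
                       spacing = c(2.73, 2.73, 2.79)) {
  stopifnot(inherits(config, "network_config"))
  L <- config$levels
  ch <- unet_channels(config)
  params <- list()
  add_convblock <- function(prefix, cin, cout) {
    params[[paste0(prefix, ".conv1.W")]] <<- he_init(cout, 27 * cin, 27 * cin)
    params[[paste0(prefix, ".conv1.b")]] <<- numeric(cout)
    params[[paste0(prefix, ".in1.gamma")]] <<- rep(1, cout)
    params[[paste0(prefix, ".in1.beta")]] <<- numeric(cout)
    params[[paste0(prefix, ".conv2.W")]] <<- he_init(cout, 27 * cout, 27 * cout)
    params[[paste0(prefix, ".conv2.b")]] <<- numeric(cout)
    params[[paste0(prefix, ".in2.gamma")]] <<- rep(1, cout)
    params[[paste0(prefix, ".in2.beta")]] <<- numeric(cout)
  }
  with_seed(seed, {
    for (l in seq_len(L)) {
      cin <- if (l == 1L) config$in_channels else ch[l - 1]
      add_convblock(paste0("enc", l), cin, ch[l])
    }
    for (l in seq_len(L - 1)) {   # decoder levels, finest = 1
      params[[paste0("up", l, ".W")]] <- he_init(8 * ch[l], ch[l + 1], ch[l + 1])
      params[[paste0("up", l, ".b")]] <- numeric(ch[l])
      add_convblock(paste0("dec", l), 2 * ch[l], ch[l])
    }
    n_heads <- if (config$deep_supervision) L else 1L
    for (s in seq_len(n_heads)) {
      # scoring heads start at zero: initial scores are exactly tied (argmax
      # falls to background) and the short-schedule optimizer spends its
      # movement budget on signal rather than on cancelling init noise
      params[[paste0("head", s, ".W")]] <- matrix(0, 3, ch[s])
      params[[paste0("head", s, ".b")]] <- numeric(3)
    }
  })
  structure(list(params = params, net_cfg = config, spacing = spacing,
                 train_cfg = NULL, history = NULL, trained = FALSE,
                 seed = as.integer(seed), symmetrized = FALSE,
                 version = "srfpet-1"),
            class = "srf_model")
}

check_patch_edge <- function(dims, levels) {
  div <- 2^(levels - 1)
  if (any(dims %% div != 0))
    stopf("patch dimensions must be divisible by %d (2^(levels-1)) for a %d-level network",
          div, levels)
}

# Stack the two input channels, applying the fixed affine rescale.
make_input <- function(ct_arr, pet_arr, cfg) {
  d <- dim(ct_arr)
  x <- array(0, c(d, 2))
  if (cfg$rescale_input) {
    x[, , , 1] <- ct_arr / 100
    x[, , , 2] <- pet_arr / 10
  } else {
    x[, , , 1] <- ct_arr
    x[, , , 2] <- pet_arr
  }
  x
}

IN_EPS <- 1e-5

# conv -> instance norm -> ReLU, twice.  The conv keeps its im2col matrix
# (as an external pointer) when a cache is requested, so the backward pass
# computes the weight gradient without rebuilding it.
convblock_fwd <- function(x, prefix, params, keep = TRUE, slope = 0.1) {
  c1 <- .conv3_fwd(as.double(x), dim(x), params[[paste0(prefix, ".conv1.W")]],
                   params[[paste0(prefix, ".conv1.b")]], keep)
  n1 <- .in_relu_fwd(c1$y, dim(c1$y), params[[paste0(prefix, ".in1.gamma")]],
                     params[[paste0(prefix, ".in1.beta")]], IN_EPS, slope)
  c2 <- .conv3_fwd(n1$out, dim(n1$out), params[[paste0(prefix, ".conv2.W")]],
                   params[[paste0(prefix, ".conv2.b")]], keep)
  n2 <- .in_relu_fwd(c2$y, dim(c2$y), params[[paste0(prefix, ".in2.gamma")]],
                     params[[paste0(prefix, ".in2.beta")]], IN_EPS, slope)
  cache <- if (keep) list(dims_x = dim(x), c1 = c1, n1 = n1, c2 = c2, n2 = n2)
  list(out = n2$out, cache = cache)
}

convblock_bwd <- function(dout, prefix, params, cache, grads, slope = 0.1) {
  d2 <- dim(cache$c2$y)
  b2 <- .in_relu_bwd(cache$c2$y, d2, dout,
                     params[[paste0(prefix, ".in2.gamma")]],
                     params[[paste0(prefix, ".in2.beta")]],
                     cache$n2$mu, cache$n2$inv_sd, slope)
  grads[[paste0(prefix, ".in2.gamma")]] <- b2$dgamma
  grads[[paste0(prefix, ".in2.beta")]] <- b2$dbeta
  c2 <- .conv3_bwd(cache$c2$cols, dim(cache$n1$out),
                   params[[paste0(prefix, ".conv2.W")]], b2$dx)
  grads[[paste0(prefix, ".conv2.W")]] <- c2$dW
  grads[[paste0(prefix, ".conv2.b")]] <- c2$db
  d1 <- dim(cache$c1$y)
  b1 <- .in_relu_bwd(cache$c1$y, d1, c2$dx,
                     params[[paste0(prefix, ".in1.gamma")]],
                     params[[paste0(prefix, ".in1.beta")]],
                     cache$n1$mu, cache$n1$inv_sd, slope)
  grads[[paste0(prefix, ".in1.gamma")]] <- b1$dgamma
  grads[[paste0(prefix, ".in1.beta")]] <- b1$dbeta
  c1 <- .conv3_bwd(cache$c1$cols, cache$dims_x,
                   params[[paste0(prefix, ".conv1.W")]], b1$dx)
  grads[[paste0(prefix, ".conv1.W")]] <- c1$dW
  grads[[paste0(prefix, ".conv1.b")]] <- c1$db
  list(dx = c1$dx, grads = grads)
}

conv1x1_fwd <- function(x, W, b) {
  d <- dim(x); N <- prod(d[1:3])
  y <- matrix(x, N, d[4]) %*% t(W)
  y <- sweep(y, 2, b, `+`)
  array(y, c(d[1:3], nrow(W)))
}

conv1x1_bwd <- function(x, W, dy) {
  d <- dim(x); N <- prod(d[1:3])
  dym <- matrix(dy, N, nrow(W))
  xm <- matrix(x, N, d[4])
  list(dW = t(dym) %*% xm, db = colSums(dym),
       dx = array(dym %*% W, d))
}

# Forward pass.  Returns per-scale score maps (finest first) and, when
# `want_cache`, everything needed for the backward pass.
unet_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$net_cfg; params <- model$params
  L <- cfg$levels
  slope <- cfg$relu_slope %||% 0.1
  d <- dim(x)
  if (length(d) != 4L || d[4] != cfg$in_channels)
    stopf("input must be a (nx, ny, nz, 2) array")
  check_patch_edge(d[1:3], L)
  enc <- vector("list", L); pool <- vector("list", L)
  cur <- x
  for (l in seq_len(L)) {
    if (l > 1L) {
      mp <- .maxpool_fwd(as.double(cur), dim(cur))
      pool[[l]] <- mp
      cur <- mp$y
    }
    blk <- convblock_fwd(cur, paste0("enc", l), params, keep = want_cache,
                         slope = slope)
    enc[[l]] <- blk
    cur <- blk$out
  }
  dec <- vector("list", L - 1); ups <- vector("list", L - 1)
  feats <- vector("list", L)       # feature map at each scale
  feats[[L]] <- enc[[L]]$out
  if (L > 1) {
    for (l in rev(seq_len(L - 1))) {
      up <- .upconv_fwd(as.double(feats[[l + 1]]), dim(feats[[l + 1]]),
                        params[[paste0("up", l, ".W")]],
                        params[[paste0("up", l, ".b")]])
      skip <- enc[[l]]$out
      cat_in <- array(c(skip, up), c(dim(skip)[1:3], dim(skip)[4] + dim(up)[4]))
      blk <- convblock_fwd(cat_in, paste0("dec", l), params, keep = want_cache,
                           slope = slope)
      dec[[l]] <- blk
      ups[[l]] <- up
      feats[[l]] <- blk$out
    }
  }
  n_heads <- if (cfg$deep_supervision) L else 1L
  scores <- vector("list", n_heads)
  for (s in seq_len(n_heads))
    scores[[s]] <- conv1x1_fwd(feats[[s]], params[[paste0("head", s, ".W")]],
                               params[[paste0("head", s, ".b")]])
  out <- list(scores = scores)
  if (want_cache)
    out$cache <- list(x = x, enc = enc, pool = pool, dec = dec, feats = feats)
  out
}

# Backward pass: `dscores` is a list of gradients, one per head.
unet_backward <- function(model, cache, dscores) {
  cfg <- model$net_cfg; params <- model$params
  L <- cfg$levels
  slope <- cfg$relu_slope %||% 0.1
  grads <- list()
  n_heads <- length(dscores)
  dfeat <- vector("list", L)
  for (s in seq_len(n_heads)) {
    hb <- conv1x1_bwd(cache$feats[[s]], params[[paste0("head", s, ".W")]],
                      dscores[[s]])
    grads[[paste0("head", s, ".W")]] <- hb$dW
    grads[[paste0("head", s, ".b")]] <- hb$db
    dfeat[[s]] <- hb$dx
  }
  for (s in seq_len(L)) if (is.null(dfeat[[s]]))
    dfeat[[s]] <- array(0, dim(cache$feats[[s]]))

  denc <- vector("list", L)        # gradient wrt each encoder block output
  # decoder chain, finest to coarsest
  if (L > 1) {
    for (l in seq_len(L - 1)) {
      bb <- convblock_bwd(dfeat[[l]], paste0("dec", l), params,
                          cache$dec[[l]]$cache, grads, slope = slope)
      grads <- bb$grads
      dcat <- bb$dx
      ch_skip <- dim(cache$enc[[l]]$out)[4]
      denc[[l]] <- dcat[, , , seq_len(ch_skip), drop = FALSE]
      dup <- dcat[, , , ch_skip + seq_len(dim(dcat)[4] - ch_skip), drop = FALSE]
      ub <- .upconv_bwd(as.double(cache$feats[[l + 1]]),
                        dim(cache$feats[[l + 1]]),
                        params[[paste0("up", l, ".W")]], as.double(dup))
      grads[[paste0("up", l, ".W")]] <- ub$dW
      grads[[paste0("up", l, ".b")]] <- ub$db
      dfeat[[l + 1]] <- dfeat[[l + 1]] + ub$dx
    }
  }
  denc[[L]] <- dfeat[[L]]
  # encoder chain, deepest to shallowest
  for (l in rev(seq_len(L))) {
    bb <- convblock_bwd(denc[[l]], paste0("enc", l), params,
                        cache$enc[[l]]$cache, grads, slope = slope)
    grads <- bb$grads
    if (l > 1L) {
      dpool <- .maxpool_bwd(cache$pool[[l]]$argmax, as.double(bb$dx),
                            dim(cache$enc[[l - 1]]$out))
      denc[[l - 1]] <- denc[[l - 1]] + dpool
    }
  }
  grads
}

#' Class-weighted categorical cross-entropy
#'
#' Softmax-normalizes the 3-class scores per voxel and returns the weighted
#' mean cross-entropy, where each voxel is weighted by the weight of its
#' TRUE class and the sum is divided by the total weight. The weighted-mean
#' normalization keeps the loss magnitude patch-size invariant.
#'
#' @param scores Numeric array `(nx, ny, nz, 3)` of unnormalized scores.
#' @param labels Integer array `(nx, ny, nz)` with values in \{0, 1, 2\}.
#' @param weights A [class_weights] vector (default background 1, kidneys 5).
#' @return Non-negative scalar; 0 only in the limit of perfect prediction.
#' @export
weighted_ce <- function(scores, labels, weights = class_weights()) {
  d <- dim(scores)
  if (length(d) != 4L || d[4] != 3L) stopf("`scores` must be (nx, ny, nz, 3)")
  if (!identical(d[1:3], dim(labels)))
    stopf("`scores` and `labels` must be spatially aligned")
  if (!all(is.finite(scores))) stopf("non-finite scores")
  if (!all(labels %in% c(0L, 1L, 2L))) stopf("labels must be in {0, 1, 2}")
  N <- prod(d[1:3])
  sm <- matrix(scores, N, 3)
  m <- pmax(sm[, 1], sm[, 2], sm[, 3])
  lse <- m + log(exp(sm[, 1] - m) + exp(sm[, 2] - m) + exp(sm[, 3] - m))
  idx <- cbind(seq_len(N), as.integer(labels) + 1L)
  logp <- sm[idx] - lse
  w <- unclass(weights)[as.integer(labels) + 1L]
  -sum(w * logp) / sum(w)
}

# Gradient of weighted_ce with respect to the scores.
weighted_ce_grad <- function(scores, labels, weights = class_weights()) {
  d <- dim(scores)
  N <- prod(d[1:3])
  sm <- matrix(scores, N, 3)
  m <- pmax(sm[, 1], sm[, 2], sm[, 3])
  e <- exp(sm - m)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(N), as.integer(labels) + 1L)
  p[idx] <- p[idx] - 1
  w <- unclass(weights)[as.integer(labels) + 1L]
  array(p * (w / sum(w)), d)
}

# Nearest-neighbour label downsampling by 2^(s-1) for deep supervision;
# the representative voxel of each 2x2x2 block is its low-index corner.
downsample_labels <- function(labels, s) {
  for (i in seq_len(s - 1)) {
    d <- dim(labels)
    labels <- labels[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2),
                     drop = FALSE]
  }
  labels
}

default_scale_weights <- function(n) 0.5^(seq_len(n) - 1)

#' Deep-supervision loss
#'
#' Weighted combination of the class-weighted cross-entropy at every model
#' scale: labels are downsampled to each scale by nearest neighbour and the
#' per-scale losses combined as
#' `sum(scale_weights * ce) / sum(scale_weights)`. The default scale
#' weights halve per scale (finest first), emphasizing the full-resolution
#' output.
#'
#' @param per_scale_scores List of score arrays, finest first, coarsest last.
#' @param labels Full-resolution integer label array.
#' @param weights A [class_weights].
#' @param scale_weights Positive weights, one per scale.
#' @return Non-negative scalar.
#' @export
deep_supervision_loss <- function(per_scale_scores, labels,
                                  weights = class_weights(),
                                  scale_weights = NULL) {
  n <- length(per_scale_scores)
  if (is.null(scale_weights)) scale_weights <- default_scale_weights(n)
  if (length(scale_weights) != n)
    stopf("`scale_weights` must have one entry per scale (%d)", n)
  if (any(scale_weights < 0) || sum(scale_weights) <= 0)
    stopf("`scale_weights` must be >= 0 with positive sum")
  u <- scale_weights / sum(scale_weights)
  tot <- 0
  for (s in seq_len(n)) {
    if (u[s] == 0) next
    tot <- tot + u[s] * weighted_ce(per_scale_scores[[s]],
                                    downsample_labels(labels, s), weights)
  }
  tot
}

ds_loss_grad <- function(per_scale_scores, labels, weights = class_weights(),
                         scale_weights = NULL) {
  n <- length(per_scale_scores)
  if (is.null(scale_weights)) scale_weights <- default_scale_weights(n)
  u <- scale_weights / sum(scale_weights)
  lapply(seq_len(n), function(s) {
    if (u[s] == 0) return(array(0, dim(per_scale_scores[[s]])))
    u[s] * weighted_ce_grad(per_scale_scores[[s]],
                            downsample_labels(labels, s), weights)
  })
}

# Per-voxel softmax probabilities (used by tests and inference diagnostics).
softmax_scores <- function(scores) {
  d <- dim(scores); N <- prod(d[1:3])
  sm <- matrix(scores, N, 3)
  m <- pmax(sm[, 1], sm[, 2], sm[, 3])
  e <- exp(sm - m)
  array(e / rowSums(e), d)
}
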