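# Small shared fixtures, built in code.

tiny_phantom_spec <- function(seed = 1L, ...) {
  # 32^3 grid: single-patch inference, fast to paint
  fov <- 32 * c(2.73, 2.73, 2.79)
  phantom_spec(shape = c(32, 32, 32),
               left = kidney_spec(center = c(62, 44, 44),
                                  semi_axes = c(13, 10, 18)),
               right = kidney_spec(center = c(fov[1] - 62, 44, 44),
                                   semi_axes = c(13, 10, 18)),
               bladder = list(center = c(fov[1] / 2, 44, 10), radius = 6,
                              suv = 60, hu = 10),
               organs = list(
                 list(center = c(0.29, 0.43, 0.77) * fov, radius = 14,
                      suv = 12, hu = 60),
                 list(center = c(0.78, 0.46, 0.77) * fov, radius = 6.5,
                      suv = 6, hu = 45)),
               seed = seed, ...)
}

# A quickly trained desk model on tiny symmetric phantoms, cached across
# tests within one run.
.tiny_model_env <- new.env()
tiny_trained_model <- function() {
  if (is.null(.tiny_model_env$model)) {
    cohort <- lapply(1:4, function(i) generate_phantom(tiny_phantom_spec(seed = i)))
    # helper model for inference-path tests: small budget, so a faster
    # learning rate than the production recipe
    cfg <- train_config(patch_edge = 32L, samples_per_epoch = 64L,
                        epochs = 10L, batch_size = 1L, lr0 = 2e-3,
                        augment = NULL, seed = 11L)
    net <- network_config(levels = 2L, base_channels = 8L)
    .tiny_model_env$model <- train_model(cohort, net, cfg)
  }
  .tiny_model_env$model
}
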