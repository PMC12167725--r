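# S3 methods for the fitted segmentation model.

#' @export
print.srf_model <- function(x, ...) {
  cfg <- x$net_cfg
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<srf_model> 3D U-Net, %d levels, %d base channels, %s parameters\n",
              cfg$levels, cfg$base_channels, format(n_par, big.mark = ",")))
  cat(sprintf("  input: 2 channels (CT HU, PET SUV) on a %s mm grid\n",
              paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  deep supervision: %s; trained: %s%s\n",
              cfg$deep_supervision, x$trained,
              if (isTRUE(x$symmetrized)) "; mirror-symmetrized" else ""))
  if (!is.null(x$history))
    cat(sprintf("  final training loss: %.4f after %d epochs\n",
                tail(x$history$loss, 1), nrow(x$history)))
  invisible(x)
}

#' @export
summary.srf_model <- function(object, ...) {
  print(object)
  if (!is.null(object$train_cfg)) {
    tc <- object$train_cfg
    cat(sprintf("  recipe: %d^3 patches, %d epochs x %d samples, batch %d, lr0 %.2g (-%.1f%%/epoch)\n",
                tc$patch_edge, tc$epochs, tc$samples_per_epoch, tc$batch_size,
                tc$lr0, 100 * tc$lr_decay_per_epoch))
  }
  invisible(object)
}

#' Segment a study with a trained model
#'
#' Convenience method around [segment_and_measure].
#'
#' @param object A trained `srf_model`.
#' @param ct,pet Co-registered CT and PET [image_volume]s.
#' @param ... Unused.
#' @return List with `labels` and `result` (see [segment_and_measure]).
#' @export
predict.srf_model <- function(object, ct, pet, ...) {
  segment_and_measure(ct, pet, object)
}

#' Plot the training history of a model
#'
#' @param x A trained `srf_model`.
#' @param ... Passed to [graphics::plot].
#' @return `x`, invisibly.
#' @export
plot.srf_model <- function(x, ...) {
  if (is.null(x$history)) stopf("model has no training history")
  graphics::plot(x$history$epoch, x$history$loss, type = "b",
                 xlab = "epoch", ylab = "mean training loss", ...)
  invisible(x)
}
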