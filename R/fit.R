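#' Fit an airway segmentation U-Net
#'
#' The package's central fitting function: builds the hybrid-padding 3D
#' U-Net, trains it on the given samples with the ROI-masked soft Dice loss
#' under the configured protocol, and returns a fitted-model object with
#' `print`, `summary`, `coef`, `plot` and `predict` methods. `predict` runs
#' sliding-window overlap-averaged inference followed by the rule-based
#' post-processing into a single connected airway tree.
#'
#' @param samples list of [airway_sample]s (e.g. from
#'   [sample_from_phantom()]); at least 2.
#' @param unet a [unet_config].
#' @param train a [train_config]; its `patch_size` must be admissible for
#'   the network.
#' @param augment an [augment_config].
#' @param verbose print per-epoch losses.
#' @return an `airway_unet` object.
#' @export
airway_unet <- function(samples,
                        unet = unet_config(),
                        train = train_config(),
                        augment = augment_config(),
                        verbose = FALSE) {
  model <- build_unet(unet)
  fit <- train_unet(model, samples, train, augment, verbose = verbose)
  structure(list(model = fit$model, history = fit$history,
                 val_ids = fit$val_ids, unet = unet, train = train,
                 augment = augment, n_samples = length(samples)),
            class = "airway_unet")
}

#' @export
print.airway_unet <- function(x, ...) {
  cat("Airway segmentation U-Net\n")
  cat(sprintf("  architecture : %d levels (%d valid), %d first-level features, %s parameters\n",
              x$unet$n_levels, x$unet$n_valid_levels, x$unet$n_features_first,
              format(n_params(x$model), big.mark = ",")))
  cat(sprintf("  training     : %d samples (%d validation), patch %s, %d epochs\n",
              x$n_samples, length(x$val_ids),
              paste(x$train$patch_size, collapse = "x"),
              length(x$history$val_loss)))
  cat(sprintf("  best val loss: %.4f at epoch %d (stopped: %s)\n",
              min(x$history$val_loss), x$history$best_epoch, x$history$stop_reason))
  invisible(x)
}

#' @export
summary.airway_unet <- function(object, ...) {
  h <- object$history
  out <- list(
    n_parameters = n_params(object$model),
    epochs = length(h$val_loss),
    best_epoch = h$best_epoch,
    best_val_loss = min(h$val_loss),
    final_train_loss = tail(h$train_loss, 1),
    stop_reason = h$stop_reason,
    validation_samples = object$val_ids)
  class(out) <- "summary.airway_unet"
  out
}

#' @export
print.summary.airway_unet <- function(x, ...) {
  cat(sprintf("U-Net fit: %s parameters, %d epochs (stop: %s)\n",
              format(x$n_parameters, big.mark = ","), x$epochs, x$stop_reason))
  cat(sprintf("  best validation loss %.4f at epoch %d; final training loss %.4f\n",
              x$best_val_loss, x$best_epoch, x$final_train_loss))
  cat("  validation samples:", paste(x$validation_samples, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.airway_unet <- function(object, ...) object$model$params

#' Plot training and validation loss curves
#' @param x an `airway_unet`.
#' @param ... passed to `plot`.
#' @export
plot.airway_unet <- function(x, ...) {
  h <- x$history
  e <- seq_along(h$val_loss)
  plot(e, h$train_loss, type = "l", col = "grey40", ylim = range(c(h$train_loss, h$val_loss)),
       xlab = "epoch", ylab = "soft Dice loss", ...)
  lines(e, h$val_loss, col = "firebrick")
  abline(v = h$best_epoch, lty = 3)
  legend("topright", c("training", "validation"), col = c("grey40", "firebrick"),
         lty = 1, bty = "n")
  invisible(x)
}

#' Predict an airway tree from an intensity volume
#'
#' Normalizes intensities with the training window, runs sliding-window
#' inference with the training patch size, and post-processes: lung
#' masking, thresholding, central-airway merge and largest connected
#' component. `exact_mode` switches to the benchmark-submission convention
#' of threshold 0.1 with 6-connectivity.
#'
#' @param object a fitted `airway_unet`.
#' @param image intensity [volume_grid] in stored (HU-like) units.
#' @param lung_mask binary lung mask, or `"auto"` to run [segment_lungs()].
#' @param central_mask binary trachea/main-bronchi mask, `"auto"` to run
#'   [segment_central_airways()], or NULL to skip the merge.
#' @param threshold probability threshold (default 0.5).
#' @param connectivity 26 (default) or 6.
#' @param exact_mode use threshold 0.1 and 6-connectivity.
#' @param overlap sliding-window overlap fraction.
#' @param type `"mask"` for the final binary tree, `"probability"` for the
#'   aggregated probability map (no post-processing).
#' @param ... unused.
#' @return a [volume_grid].
#' @export
predict.airway_unet <- function(object, image, lung_mask = "auto",
                                central_mask = NULL, threshold = 0.5,
                                connectivity = 26L, exact_mode = FALSE,
                                overlap = 0.5, type = c("mask", "probability"),
                                ...) {
  type <- match.arg(type)
  if (exact_mode) { threshold <- 0.1; connectivity <- 6L }
  norm <- normalize_intensity(image, object$train$intensity_window)
  prob <- predict_volume(object$model, norm, object$train$patch_size, overlap)
  if (type == "probability") return(prob)
  if (identical(lung_mask, "auto")) lung_mask <- segment_lungs(image)
  if (identical(central_mask, "auto")) central_mask <- segment_central_airways(image)
  extract_airway_tree(prob, lung_mask, central_mask, threshold, connectivity)
}
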