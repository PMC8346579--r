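#' Assemble a training sample
#'
#' @param image intensity [volume_grid].
#' @param labels binary ground-truth airway lumen mask.
#' @param roi_mask binary lung-field mask defining the loss region.
#' @param id sample identifier (used for the deterministic train/validation
#'   split).
#' @return an `airway_sample`.
#' @export
airway_sample <- function(image, labels, roi_mask, id = "sample") {
  check_aligned(image, labels, roi_mask, what = "sample grids")
  structure(list(image = image, labels = labels, roi_mask = roi_mask,
                 id = as.character(id)), class = "airway_sample")
}

#' Training sample from a phantom
#'
#' Pairs the phantom image with its exact lumen ground truth and lung-field
#' region of interest.
#'
#' @param phantom an `airway_phantom`.
#' @param id sample identifier.
#' @return an `airway_sample`.
#' @export
sample_from_phantom <- function(phantom, id = sprintf("phantom-%d", phantom$config$seed)) {
  airway_sample(phantom$image, phantom$lumen_mask, phantom$lung_mask, id)
}

#' Clip-and-rescale intensity normalization
#'
#' Clips intensities to `window` and rescales linearly to \[0,1\] before the
#' network sees them.
#'
#' @param image intensity [volume_grid] or array.
#' @param window length-2 clipping window in stored intensity units.
#' @return normalized [volume_grid].
#' @export
normalize_intensity <- function(image, window = c(-1000, 500)) {
  v <- pmin(pmax(unclass(image), window[1]), window[2])
  vg_like(array((v - window[1]) / (window[2] - window[1]), dim(image)), image)
}

#' Crop a sample to the ROI bounding box with a safety buffer
#'
#' Crops image, labels and ROI to the bounding box of the ROI mask expanded
#' by `buffer_voxels` in every direction (clamped to the volume), and masks
#' the labels by the ROI — removing the trachea-analogue and anything else
#' outside the lung fields from the training target.
#'
#' @param sample an [airway_sample].
#' @param buffer_voxels buffer around the ROI bounding box (default 30).
#' @return the cropped [airway_sample].
#' @export
crop_to_roi_bbox <- function(sample, buffer_voxels = 30L) {
  roi <- unclass(sample$roi_mask)
  if (!any(roi > 0)) stop("roi_mask is empty; cannot crop to its bounding box")
  idx <- which(roi > 0, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - buffer_voxels, 1L)
  hi <- pmin(apply(idx, 2, max) + buffer_voxels, dim(roi))
  sl <- function(g) vg_like(unclass(g)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE], g)
  labels <- sl(sample$labels)
  roi_c <- sl(sample$roi_mask)
  labels <- vg_like(unclass(labels) * (unclass(roi_c) > 0), labels)
  airway_sample(sl(sample$image), labels, roi_c, sample$id)
}

# internal: symmetric zero-pad a sample to at least `target` per axis
pad_sample_to <- function(sample, target) {
  d <- dim(sample$image)
  need <- pmax(target - d, 0L)
  if (all(need == 0L)) return(sample)
  lo <- need %/% 2L
  pad1 <- function(g) {
    out <- array(0, pmax(d, target))
    out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <-
      unclass(g)
    vg_like(out, g)
  }
  airway_sample(pad1(sample$image), pad1(sample$labels), pad1(sample$roi_mask), sample$id)
}

#' Sample a random patch from a training sample
#'
#' Draws the first corner `(x0, y0, z0)` uniformly from
#' `[0, D-d] x [0, W-w] x [0, H-h]` and extracts the half-open window of size
#' `patch_size` from image, labels and ROI alike. Uses the current RNG state.
#'
#' @param sample an [airway_sample] at least as large as the patch.
#' @param patch_size integer triple `(d, w, h)`.
#' @return a `patch_pair`: list with `image_patch`, `label_patch`,
#'   `roi_patch` and the 0-based `corner`.
#' @export
sample_random_patch <- function(sample, patch_size) {
  d <- dim(sample$image)
  patch_size <- as.integer(rep(patch_size, length.out = 3L))
  if (any(patch_size > d))
    stop("patch size ", paste(patch_size, collapse = "x"),
         " exceeds sample size ", paste(d, collapse = "x"))
  corner <- vapply(1:3, function(a) {
    hi <- d[a] - patch_size[a]
    if (hi == 0L) 0L else as.integer(sample.int(hi + 1L, 1L) - 1L)
  }, integer(1))
  win <- function(g) {
    vg_like(unclass(g)[corner[1] + seq_len(patch_size[1]),
                       corner[2] + seq_len(patch_size[2]),
                       corner[3] + seq_len(patch_size[3]), drop = FALSE], g)
  }
  structure(list(image_patch = win(sample$image), label_patch = win(sample$labels),
                 roi_patch = win(sample$roi_mask), corner = corner),
            class = "patch_pair")
}

#' Augmentation configuration
#'
#' Rigid-transform data augmentation for training patches: per-axis random
#' flips, small 3D rotations and isotropic scaling. The image is resampled
#' with trilinear interpolation, labels and ROI with nearest neighbour, in a
#' single composed resampling pass.
#'
#' @param flip_axes logical triple: allow flipping along each axis.
#' @param max_rotation_deg maximum per-axis rotation angle (degrees).
#' @param scale_range isotropic scale factor interval.
#' @param enabled master switch.
#' @param fill_value intensity used outside the patch after resampling, in
#'   normalized units. The default 0.1 is lung parenchyma under the standard
#'   \[-1000, 500\] window — the background an airway patch is embedded in;
#'   filling with 0 (air) would paint lumen-valued slabs labelled background.
#' @return an `augment_config`.
#' @export
augment_config <- function(flip_axes = c(TRUE, TRUE, TRUE),
                           max_rotation_deg = 10,
                           scale_range = c(0.75, 1.25),
                           enabled = TRUE,
                           fill_value = 0.1) {
  if (max_rotation_deg < 0) stop("max_rotation_deg must be >= 0")
  if (any(scale_range <= 0) || scale_range[2] < scale_range[1])
    stop("scale_range must be a positive, ordered interval")
  structure(list(flip_axes = as.logical(flip_axes),
                 max_rotation_deg = max_rotation_deg,
                 scale_range = as.numeric(scale_range),
                 enabled = isTRUE(enabled), fill_value = fill_value),
            class = "augment_config")
}

#' Apply a rigid transform (flips, rotation, scaling) to a patch pair
#'
#' Deterministic core of the augmentation: flips, per-axis Euler rotations
#' and isotropic scaling are composed into one affine map about the patch
#' centre and applied in a single resampling (trilinear for the image,
#' nearest neighbour for labels and ROI, which therefore stay binary).
#'
#' @param pair a `patch_pair`.
#' @param flips logical triple.
#' @param angles_deg numeric triple of rotation angles about x, y, z.
#' @param scale isotropic scale factor.
#' @param fill image fill value outside the source patch.
#' @return the transformed `patch_pair`.
#' @export
apply_rigid <- function(pair, flips = c(FALSE, FALSE, FALSE),
                        angles_deg = c(0, 0, 0), scale = 1, fill = 0) {
  d <- dim(pair$image_patch)
  a <- angles_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
  Fm <- diag(ifelse(flips, -1, 1))
  fwd <- (scale * Rx %*% Ry %*% Rz) %*% Fm
  inv <- solve(fwd)
  centre <- (d - 1) / 2
  off <- centre - inv %*% centre
  M <- cbind(inv, off) # 3x4, output voxel -> input voxel
  Mv <- as.numeric(t(M))
  res <- function(g, nearest, fl) {
    vg_like(.affine_resample(vg_values(g), Mv, nearest, fl), g)
  }
  structure(list(image_patch = res(pair$image_patch, FALSE, fill),
                 label_patch = res(pair$label_patch, TRUE, 0),
                 roi_patch = res(pair$roi_patch, TRUE, 0),
                 corner = pair$corner), class = "patch_pair")
}

#' Randomly augment a patch pair
#'
#' Draws flips (probability 0.5 per enabled axis), per-axis rotation angles
#' uniform in `[-max_rotation_deg, max_rotation_deg]` and one isotropic
#' scale factor uniform in `scale_range`, then applies [apply_rigid()].
#' Uses the current RNG state.
#'
#' @param pair a `patch_pair`.
#' @param config an [augment_config].
#' @return the augmented `patch_pair`.
#' @export
augment_patch <- function(pair, config = augment_config()) {
  if (!config$enabled) return(pair)
  flips <- config$flip_axes & (runif(3) < 0.5)
  angles <- runif(3, -config$max_rotation_deg, config$max_rotation_deg)
  scale <- runif(1, config$scale_range[1], config$scale_range[2])
  apply_rigid(pair, flips, angles, scale, config$fill_value)
}

#' ROI-masked soft Dice loss
#'
#' `1 - 2 * sum(p*g) / (sum(p) + sum(g) + eps)` with all sums restricted to
#' the region of interest, so voxels outside the ROI influence neither the
#' value nor the gradient. `eps` defines the empty-ROI / empty-truth case.
#'
#' @param pred probability patch `p(x)` in \[0,1\].
#' @param truth binary ground-truth patch `g(x)`.
#' @param roi binary ROI patch defining the summation region.
#' @param eps smoothing constant.
#' @return scalar loss in \[0,1\].
#' @export
masked_soft_dice_loss <- function(pred, truth, roi, eps = 1e-6) {
  check_aligned(pred, truth, roi, what = "loss inputs")
  r <- unclass(roi) > 0
  p <- unclass(pred)[r]; g <- unclass(truth)[r]
  1 - 2 * sum(p * g) / (sum(p) + sum(g) + eps)
}

# internal: loss and gradient w.r.t. pred (full-size array, zero outside ROI)
soft_dice_loss_grad <- function(pred, truth, roi, eps = 1e-6) {
  r <- unclass(roi) > 0
  p <- unclass(pred); g <- unclass(truth)
  I <- sum(p[r] * g[r]); Sp <- sum(p[r]); Sg <- sum(g[r])
  D <- Sp + Sg + eps
  grad <- array(0, dim(p))
  grad[r] <- -2 * g[r] / D + 2 * I / D^2
  list(loss = 1 - 2 * I / D, grad = grad)
}

#' Training protocol configuration
#'
#' Mirrors the reference training protocol: Adam with learning rate 1e-4,
#' 8 random patches per scan per epoch in batches of one, an 80/20
#' train/validation split, and a convergence rule on the moving average of
#' the validation loss over `ma_window_epochs`: stop when, relative to its
#' value `stop_patience_epochs` earlier, it rises by more than
#' `stop_rise_fraction` or fails to fall by more than
#' `stop_stall_fraction`. The model returned is the snapshot at the overall
#' minimum validation loss.
#'
#' @param learning_rate Adam learning rate.
#' @param patches_per_scan_per_epoch random patches drawn per training scan
#'   and epoch.
#' @param batch_size patches per optimizer step.
#' @param val_fraction fraction of samples held out for validation.
#' @param ma_window_epochs moving-average window (epochs).
#' @param stop_rise_fraction relative rise that triggers stopping.
#' @param stop_stall_fraction minimum relative fall required to continue.
#' @param stop_patience_epochs look-back distance for the stopping rule.
#' @param max_epochs hard epoch cap.
#' @param patch_size input patch size (must be admissible for the network).
#' @param intensity_window clip window for intensity normalization.
#' @param buffer_voxels ROI bounding-box buffer applied in preprocessing.
#' @param seed master seed for split, sampling and augmentation.
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4,
                         patches_per_scan_per_epoch = 8L,
                         batch_size = 1L,
                         val_fraction = 0.2,
                         ma_window_epochs = 50L,
                         stop_rise_fraction = 0.05,
                         stop_stall_fraction = 0.001,
                         stop_patience_epochs = 20L,
                         max_epochs = 1000L,
                         patch_size = c(252L, 252L, 252L),
                         intensity_window = c(-1000, 500),
                         buffer_voxels = 30L,
                         seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1) stop("val_fraction must lie in (0,1)")
  if (ma_window_epochs < 1L || stop_patience_epochs < 1L)
    stop("convergence windows must be positive")
  structure(list(learning_rate = learning_rate,
                 patches_per_scan_per_epoch = as.integer(patches_per_scan_per_epoch),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 ma_window_epochs = as.integer(ma_window_epochs),
                 stop_rise_fraction = stop_rise_fraction,
                 stop_stall_fraction = stop_stall_fraction,
                 stop_patience_epochs = as.integer(stop_patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 patch_size = as.integer(rep(patch_size, length.out = 3L)),
                 intensity_window = as.numeric(intensity_window),
                 buffer_voxels = as.integer(buffer_voxels),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Convergence check on the validation-loss moving average
#'
#' Never signals a stop before `ma_window_epochs + stop_patience_epochs`
#' epochs. After that, compares the current moving average with its value
#' `stop_patience_epochs` epochs earlier: a rise by more than
#' `stop_rise_fraction`, or a fall by no more than `stop_stall_fraction`,
#' stops training.
#'
#' @param history a `training_history` (or list with a `val_loss` vector).
#' @param config a [train_config].
#' @return list with `stop` (logical) and `reason`
#'   (`"rise"`, `"stall"` or `NA`).
#' @export
convergence_check <- function(history, config) {
  v <- history$val_loss
  n <- length(v)
  w <- config$ma_window_epochs
  pat <- config$stop_patience_epochs
  if (n < w + pat) return(list(stop = FALSE, reason = NA_character_))
  ma <- function(t) mean(v[(t - w + 1):t])
  cur <- ma(n); ref <- ma(n - pat)
  if (cur > ref * (1 + config$stop_rise_fraction))
    return(list(stop = TRUE, reason = "rise"))
  if ((ref - cur) <= config$stop_stall_fraction * abs(ref))
    return(list(stop = TRUE, reason = "stall"))
  list(stop = FALSE, reason = NA_character_)
}

# internal: deterministic train/validation split by sorted id + seeded shuffle
split_samples <- function(samples, val_fraction, seed) {
  ids <- vapply(samples, `[[`, character(1), "id")
  ord <- order(ids)
  shuffled <- with_local_seed(derive_seed(seed, "split"), sample(ord))
  n_val <- max(1L, round(val_fraction * length(samples)))
  if (n_val >= length(samples)) stop("need at least one training sample after the split")
  list(val = shuffled[seq_len(n_val)], train = shuffled[-seq_len(n_val)])
}

#' Train a U-Net on airway samples
#'
#' Full optimization loop: preprocesses each sample (intensity
#' normalization, ROI bounding-box crop with buffer, label masking, padding
#' up to the patch size where needed), splits train/validation
#' deterministically, then per epoch draws the configured number of random
#' augmented patches per training scan and optimizes the ROI-masked soft
#' Dice loss with Adam. Validation loss is computed on deterministic
#' (seeded) patches without augmentation. Training stops per
#' [convergence_check()] or at `max_epochs`; the returned model is the
#' snapshot with the overall minimum validation loss.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param samples list of [airway_sample]s (at least 2).
#' @param config a [train_config].
#' @param augment an [augment_config].
#' @param verbose print per-epoch losses.
#' @return list with `model` (best snapshot), `history`
#'   (a `training_history`), and the validation sample ids.
#' @export
train_unet <- function(model, samples, config = train_config(),
                       augment = augment_config(), verbose = FALSE) {
  if (length(samples) < 2L) stop("need >= 2 samples (>= 1 train, >= 1 validation)")
  if (!is_admissible_input(model$config, config$patch_size))
    stop("patch size ", paste(config$patch_size, collapse = "x"),
         " is not admissible for this network; nearest per-axis sizes: ",
         paste(vapply(config$patch_size, function(n)
           nearest_admissible(model$config, n), 1L), collapse = ", "))
  tab <- compute_shape_table(model$config, config$patch_size)
  m <- tab$margin
  prep <- lapply(samples, function(s) {
    s$image <- normalize_intensity(s$image, config$intensity_window)
    s <- crop_to_roi_bbox(s, config$buffer_voxels)
    pad_sample_to(s, config$patch_size)
  })
  sp <- split_samples(prep, config$val_fraction, config$seed)
  train_set <- prep[sp$train]; val_set <- prep[sp$val]

  params <- model$params
  zero_like <- function(x) if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
  mom <- lapply(params, zero_like)
  vel <- lapply(params, zero_like)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0L
  crop3 <- function(g) {
    d <- dim(g)
    unclass(g)[(m[1] + 1):(d[1] - m[1]), (m[2] + 1):(d[2] - m[2]),
               (m[3] + 1):(d[3] - m[3]), drop = FALSE]
  }
  eval_val <- function() {
    losses <- numeric(0)
    for (i in seq_along(val_set)) {
      with_local_seed(derive_seed(config$seed, "val-patches", i), {
        for (k in seq_len(config$patches_per_scan_per_epoch)) {
          pp <- sample_random_patch(val_set[[i]], config$patch_size)
          fw <- forward_unet(list(config = model$config, params = params) |>
                               structure(class = "unet_model"),
                             vg_values(pp$image_patch))
          losses <- c(losses, masked_soft_dice_loss(
            fw$out, crop3(pp$label_patch), crop3(pp$roi_patch)))
        }
      })
    }
    mean(losses)
  }

  history <- list(train_loss = numeric(0), val_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  stop_reason <- "max_epochs"
  with_local_seed(derive_seed(config$seed, "train-loop"), {
    for (epoch in seq_len(config$max_epochs)) {
      ep_losses <- numeric(0)
      acc <- NULL; acc_n <- 0L
      for (i in seq_along(train_set)) {
        for (k in seq_len(config$patches_per_scan_per_epoch)) {
          pp <- sample_random_patch(train_set[[i]], config$patch_size)
          pp <- augment_patch(pp, augment)
          mdl <- structure(list(config = model$config, params = params),
                           class = "unet_model")
          fw <- forward_unet(mdl, vg_values(pp$image_patch), want_cache = TRUE)
          lg <- soft_dice_loss_grad(fw$out, crop3(pp$label_patch), crop3(pp$roi_patch))
          ep_losses <- c(ep_losses, lg$loss)
          gz <- lg$grad * fw$out * (1 - fw$out)
          gz <- array(gz, c(dim(gz), 1L))
          grads <- backward_unet(mdl, fw$cache, gz)
          if (is.null(acc)) acc <- grads
          else for (nm in names(grads)) acc[[nm]] <- acc[[nm]] + grads[[nm]]
          acc_n <- acc_n + 1L
          if (acc_n >= config$batch_size) {
            t_step <- t_step + 1L
            for (nm in names(params)) {
              g <- acc[[nm]] / acc_n
              mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
              vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
              mh <- mom[[nm]] / (1 - b1^t_step)
              vh <- vel[[nm]] / (1 - b2^t_step)
              params[[nm]] <- params[[nm]] - config$learning_rate * mh / (sqrt(vh) + adam_eps)
            }
            acc <- NULL; acc_n <- 0L
          }
        }
      }
      vl <- eval_val()
      history$train_loss <- c(history$train_loss, mean(ep_losses))
      history$val_loss <- c(history$val_loss, vl)
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = epoch)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f%s", epoch,
                        mean(ep_losses), vl, if (best$epoch == epoch) " *" else ""))
      cc <- convergence_check(history, config)
      if (cc$stop) { stop_reason <- cc$reason; break }
    }
  })
  hist <- structure(list(train_loss = history$train_loss,
                         val_loss = history$val_loss,
                         best_epoch = best$epoch,
                         stop_reason = stop_reason), class = "training_history")
  best_model <- structure(list(config = model$config, params = best$params),
                          class = "unet_model")
  list(model = best_model, history = hist,
       val_ids = vapply(val_set, `[[`, character(1), "id"))
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("<training_history: %d epochs, best val loss %.4f at epoch %d (stop: %s)>\n",
              length(x$val_loss), min(x$val_loss), x$best_epoch, x$stop_reason))
  invisible(x)
}
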