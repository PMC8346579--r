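#' Build the hybrid-padding 3D U-Net
#'
#' Constructs the network weights: per level, `convs_per_level` k^3
#' convolutions each followed by ReLU; max pooling / learned transposed-
#' convolution upsampling between levels (the upsampling halves the channel
#' count); skip connections crop the encoder feature map centrally to the
#' decoder size and concatenate channels; a final 1x1x1 convolution with a
#' sigmoid produces a single-channel probability map. No dropout, no batch
#' normalization. Weights are Kaiming fan-in initialized with the seed
#' pinned in the config; biases start at zero.
#'
#' @param config a [unet_config].
#' @return a `unet_model`: list with `config` and a named list `params` of
#'   weight/bias arrays.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  L <- config$n_levels; k <- config$kernel_size; f <- config$pool_factor
  feats <- level_features(config)
  params <- list()
  with_local_seed(derive_seed(config$init_seed, "unet-init"), {
    kaiming <- function(cout, cin, ks) {
      fan_in <- cin * ks^3
      array(rnorm(cout * cin * ks^3, 0, sqrt(2 / fan_in)), c(cout, cin, ks, ks, ks))
    }
    for (l in seq_len(L)) {
      cin <- if (l == 1L) 1L else feats[l - 1L]
      for (j in seq_len(config$convs_per_level)) {
        cc <- if (j == 1L) cin else feats[l]
        params[[sprintf("enc%d.conv%d.w", l, j)]] <- kaiming(feats[l], cc, k)
        params[[sprintf("enc%d.conv%d.b", l, j)]] <- numeric(feats[l])
      }
    }
    for (l in rev(seq_len(L - 1L))) {
      params[[sprintf("dec%d.up.w", l)]] <- kaiming(feats[l], feats[l + 1L], f)
      params[[sprintf("dec%d.up.b", l)]] <- numeric(feats[l])
      for (j in seq_len(config$convs_per_level)) {
        cc <- if (j == 1L) 2L * feats[l] else feats[l]
        params[[sprintf("dec%d.conv%d.w", l, j)]] <- kaiming(feats[l], cc, k)
        params[[sprintf("dec%d.conv%d.b", l, j)]] <- numeric(feats[l])
      }
    }
    params[["final.w"]] <- kaiming(1L, feats[1L], 1L)
    params[["final.b"]] <- numeric(1L)
  })
  structure(list(config = config, params = params), class = "unet_model")
}

#' Number of trainable parameters
#' @param model a `unet_model`.
#' @return integer count of weights and biases.
#' @export
n_params <- function(model) sum(vapply(model$params, length, numeric(1)))

# internal: centered crop of a channels-last (x, y, z, C) feature map
crop_center4 <- function(x, m) {
  d <- dim(x)
  x[(m[1] + 1):(d[1] - m[1]), (m[2] + 1):(d[2] - m[2]),
    (m[3] + 1):(d[3] - m[3]), , drop = FALSE]
}

relu <- function(z) { z[z < 0] <- 0; z }

#' Forward pass of the U-Net
#'
#' Runs a single-channel 3D patch through the network. The output is a
#' probability patch in \[0,1\] whose spatial footprint is the centered crop
#' of the input by the shape-table margins.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param patch 3D array / [volume_grid] with an admissible shape.
#' @param want_cache keep intermediates for the backward pass (training).
#' @return list with `out` (3D probability array), `table` (the shape
#'   table), and when requested `cache`.
#' @export
forward_unet <- function(model, patch, want_cache = FALSE) {
  cfg <- model$config
  dims <- dim(patch)
  if (length(dims) != 3L) stop("patch must be a 3D array")
  tab <- compute_shape_table(cfg, dims) # errors with nearest admissible sizes
  p <- model$params
  L <- cfg$n_levels; f <- cfg$pool_factor; nc <- cfg$convs_per_level
  pad_of <- function(l) if (l <= cfg$n_valid_levels) 0L else (cfg$kernel_size - 1L) %/% 2L
  x <- array(as.numeric(patch), c(dims, 1L))
  cache <- if (want_cache) list(enc = vector("list", L), dec = vector("list", L)) else NULL
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    cl <- list(conv_in = vector("list", nc), z = vector("list", nc))
    for (j in seq_len(nc)) {
      if (want_cache) cl$conv_in[[j]] <- x
      z <- .conv3d_fw(x, p[[sprintf("enc%d.conv%d.w", l, j)]],
                      p[[sprintf("enc%d.conv%d.b", l, j)]], pad_of(l))
      if (want_cache) cl$z[[j]] <- z
      x <- relu(z)
    }
    skips[[l]] <- x
    if (l < L) {
      if (want_cache) cl$pool_in_dim <- dim(x)
      mp <- .maxpool_fw(x, f)
      if (want_cache) cl$pool_idx <- mp$idx
      x <- mp$y
    }
    if (want_cache) cache$enc[[l]] <- cl
  }
  for (l in rev(seq_len(L - 1L))) {
    cl <- list(conv_in = vector("list", nc), z = vector("list", nc))
    if (want_cache) cl$up_in <- x
    zu <- .upconv_fw(x, p[[sprintf("dec%d.up.w", l)]], p[[sprintf("dec%d.up.b", l)]], f)
    if (want_cache) cl$up_z <- zu
    up <- relu(zu)
    m <- tab$crop[, l]
    skip <- crop_center4(skips[[l]], m)
    if (want_cache) { cl$skip_margin <- m; cl$skip_dim <- dim(skips[[l]]) }
    Fc <- dim(skip)[4]
    x <- array(0, c(dim(up)[1:3], 2L * Fc))
    x[, , , seq_len(Fc)] <- skip
    x[, , , Fc + seq_len(Fc)] <- up
    for (j in seq_len(nc)) {
      if (want_cache) cl$conv_in[[j]] <- x
      z <- .conv3d_fw(x, p[[sprintf("dec%d.conv%d.w", l, j)]],
                      p[[sprintf("dec%d.conv%d.b", l, j)]], pad_of(l))
      if (want_cache) cl$z[[j]] <- z
      x <- relu(z)
    }
    if (want_cache) cache$dec[[l]] <- cl
  }
  if (want_cache) cache$final_in <- x
  z <- .conv3d_fw(x, p[["final.w"]], p[["final.b"]], 0L)
  prob <- array(1 / (1 + exp(-z)), dim(z)[1:3])
  list(out = prob, table = tab, cache = cache)
}

# internal: backward pass. gz_final is the gradient w.r.t. the final
# pre-sigmoid activation, shaped (ox, oy, oz, 1). Returns gradients named
# like model$params.
backward_unet <- function(model, cache, gz_final) {
  cfg <- model$config
  p <- model$params
  L <- cfg$n_levels; f <- cfg$pool_factor; nc <- cfg$convs_per_level
  pad_of <- function(l) if (l <= cfg$n_valid_levels) 0L else (cfg$kernel_size - 1L) %/% 2L
  grads <- list()
  bw <- .conv3d_bw(cache$final_in, p[["final.w"]], gz_final, 0L)
  grads[["final.w"]] <- bw$gw; grads[["final.b"]] <- bw$gb
  g <- bw$gx
  skip_grads <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    cl <- cache$dec[[l]]
    for (j in rev(seq_len(nc))) {
      g <- g * (cl$z[[j]] > 0)
      bw <- .conv3d_bw(cl$conv_in[[j]], p[[sprintf("dec%d.conv%d.w", l, j)]], g, pad_of(l))
      grads[[sprintf("dec%d.conv%d.w", l, j)]] <- bw$gw
      grads[[sprintf("dec%d.conv%d.b", l, j)]] <- bw$gb
      g <- bw$gx
    }
    Fc <- dim(g)[4] %/% 2L
    gskip <- g[, , , seq_len(Fc), drop = FALSE]
    gup <- g[, , , Fc + seq_len(Fc), drop = FALSE]
    m <- cl$skip_margin
    d <- cl$skip_dim
    full <- array(0, d)
    full[m[1] + seq_len(d[1] - 2 * m[1]), m[2] + seq_len(d[2] - 2 * m[2]),
         m[3] + seq_len(d[3] - 2 * m[3]), ] <- gskip
    skip_grads[[l]] <- full
    gup <- gup * (cl$up_z > 0)
    bw <- .upconv_bw(cl$up_in, p[[sprintf("dec%d.up.w", l)]], gup, f)
    grads[[sprintf("dec%d.up.w", l)]] <- bw$gw
    grads[[sprintf("dec%d.up.b", l)]] <- bw$gb
    g <- bw$gx
  }
  for (l in rev(seq_len(L))) {
    cl <- cache$enc[[l]]
    if (l < L) {
      g <- .maxpool_bw(g, cl$pool_idx, as.integer(cl$pool_in_dim))
      if (!is.null(skip_grads[[l]])) g <- g + skip_grads[[l]]
    } else if (!is.null(skip_grads[[l]])) {
      g <- g + skip_grads[[l]]
    }
    for (j in rev(seq_len(nc))) {
      g <- g * (cl$z[[j]] > 0)
      bw <- .conv3d_bw(cl$conv_in[[j]], p[[sprintf("enc%d.conv%d.w", l, j)]], g, pad_of(l))
      grads[[sprintf("enc%d.conv%d.w", l, j)]] <- bw$gw
      grads[[sprintf("enc%d.conv%d.b", l, j)]] <- bw$gb
      g <- bw$gx
    }
  }
  grads
}

#' Save a model checkpoint
#'
#' Checkpoints embed the full architecture configuration so they are
#' self-describing; optional metadata (epoch, validation loss) rides along.
#'
#' @param model a `unet_model`.
#' @param path output `.rds` path.
#' @param meta optional list of metadata.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  saveRDS(list(config = unclass(model$config), params = model$params, meta = meta), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path a checkpoint written by [save_checkpoint()].
#' @return a `unet_model` with a `meta` attribute.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(unet_config, ck$config[names(ck$config) %in% names(formals(unet_config))])
  model <- structure(list(config = cfg, params = ck$params), class = "unet_model")
  attr(model, "meta") <- ck$meta
  model
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<unet_model: %d levels (%d valid), %d first-level features, %s params>\n",
              cfg$n_levels, cfg$n_valid_levels, cfg$n_features_first,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}
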