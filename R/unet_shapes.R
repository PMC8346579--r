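#' U-Net architecture configuration
#'
#' Hyperparameters of the hybrid-padding 3D U-Net: non-padded (valid)
#' convolutions in the first `n_valid_levels` resolution levels of both the
#' encoder and the decoder, zero-padded convolutions in the remaining levels.
#' Feature channels double after each pooling and halve after each
#' upsampling; level `l` carries `n_features_first * 2^(l-1)` channels.
#' The reference model uses 5 levels, 16 first-level features and 3 valid
#' levels with an input patch of 252^3.
#'
#' @param n_levels number of resolution levels (>= 2 for a real U-Net; 1 is
#'   allowed as a degenerate single-level network).
#' @param n_features_first feature channels at the first level.
#' @param n_valid_levels how many of the first levels use valid convolutions
#'   (0 .. n_levels).
#' @param kernel_size odd convolution kernel size.
#' @param pool_factor pooling/upsampling factor.
#' @param convs_per_level convolutions per level in encoder and decoder.
#' @param init_seed seed for weight initialization (Kaiming fan-in normal).
#' @return a `unet_config` list.
#' @export
unet_config <- function(n_levels = 5L, n_features_first = 16L,
                        n_valid_levels = 3L, kernel_size = 3L,
                        pool_factor = 2L, convs_per_level = 2L,
                        init_seed = 1L) {
  cfg <- list(n_levels = as.integer(n_levels),
              n_features_first = as.integer(n_features_first),
              n_valid_levels = as.integer(n_valid_levels),
              kernel_size = as.integer(kernel_size),
              pool_factor = as.integer(pool_factor),
              convs_per_level = as.integer(convs_per_level),
              init_seed = as.integer(init_seed))
  if (cfg$n_levels < 1L) stop("n_levels must be >= 1")
  if (cfg$n_features_first < 1L) stop("n_features_first must be >= 1")
  if (cfg$n_valid_levels < 0L || cfg$n_valid_levels > cfg$n_levels)
    stop("n_valid_levels must lie in [0, n_levels]")
  if (cfg$kernel_size %% 2L != 1L || cfg$kernel_size < 1L)
    stop("kernel_size must be odd and positive")
  if (cfg$pool_factor < 2L) stop("pool_factor must be >= 2")
  if (cfg$convs_per_level < 1L) stop("convs_per_level must be >= 1")
  class(cfg) <- "unet_config"
  cfg
}

#' Feature channels at each level
#' @param config a [unet_config].
#' @return integer vector of length `n_levels`.
#' @export
level_features <- function(config) {
  config$n_features_first * 2L^(seq_len(config$n_levels) - 1L)
}

# internal: symbolic size propagation along ONE axis. Returns NULL when the
# size is inadmissible, else a list of per-level sizes and margins.
propagate_axis <- function(config, n) {
  L <- config$n_levels; k <- config$kernel_size; f <- config$pool_factor
  nc <- config$convs_per_level; V <- config$n_valid_levels
  shrink <- nc * (k - 1L)
  enc_in <- enc_post <- enc_pool <- integer(L)
  s <- as.integer(n)
  for (l in seq_len(L)) {
    enc_in[l] <- s
    s <- if (l <= V) s - shrink else s
    if (s < 1L) return(NULL)
    enc_post[l] <- s
    if (l < L) {
      if (s %% f != 0L) return(NULL)
      s <- s %/% f
      enc_pool[l] <- s
    }
  }
  dec_up <- dec_post <- crop <- integer(L)
  for (l in rev(seq_len(L - 1L))) {
    s <- s * f
    dec_up[l] <- s
    d <- enc_post[l] - s
    if (d < 0L || d %% 2L != 0L) return(NULL)
    crop[l] <- d %/% 2L
    s <- if (l <= V) s - shrink else s
    if (s < 1L) return(NULL)
    dec_post[l] <- s
  }
  margin <- (n - s)
  if (margin %% 2L != 0L) return(NULL)
  list(enc_in = enc_in, enc_post = enc_post, enc_pool = enc_pool,
       dec_up = dec_up, dec_post = dec_post, crop = crop,
       output = s, margin = margin %/% 2L)
}

#' Compute the per-level shape table of a U-Net
#'
#' Propagates spatial sizes symbolically through the network: each valid
#' convolution removes `kernel_size - 1` voxels per axis, padded levels
#' preserve size, pooling divides and upsampling multiplies by
#' `pool_factor`. Skip connections require the encoder map to be cropped
#' centrally to the decoder size, so the crop margin must split evenly.
#'
#' @param config a [unet_config].
#' @param input_shape integer triple (or scalar, recycled).
#' @return a `unet_shape_table`: per-axis per-level sizes, the skip-crop
#'   margins, the final `output_shape` and the per-side input/output `margin`.
#' @export
compute_shape_table <- function(config, input_shape) {
  if (length(input_shape) == 1L) input_shape <- rep(input_shape, 3L)
  axes <- lapply(input_shape, function(n) propagate_axis(config, as.integer(n)))
  bad <- vapply(axes, is.null, logical(1))
  if (any(bad))
    stop("inadmissible input shape ", paste(input_shape, collapse = "x"),
         " for this U-Net configuration; nearest admissible sizes per axis: ",
         paste(vapply(input_shape, function(n) nearest_admissible(config, n), 1L),
               collapse = ", "))
  tab <- list(
    input_shape = as.integer(input_shape),
    enc_in = t(vapply(axes, `[[`, integer(config$n_levels), "enc_in")),
    enc_post = t(vapply(axes, `[[`, integer(config$n_levels), "enc_post")),
    enc_pool = t(vapply(axes, `[[`, integer(config$n_levels), "enc_pool")),
    dec_up = t(vapply(axes, `[[`, integer(config$n_levels), "dec_up")),
    dec_post = t(vapply(axes, `[[`, integer(config$n_levels), "dec_post")),
    crop = t(vapply(axes, `[[`, integer(config$n_levels), "crop")),
    output_shape = vapply(axes, `[[`, integer(1), "output"),
    margin = vapply(axes, `[[`, integer(1), "margin"),
    config = config)
  class(tab) <- "unet_shape_table"
  tab
}

#' @export
print.unet_shape_table <- function(x, ...) {
  cat(sprintf("<unet_shape_table input %s -> output %s (margin %s per side)>\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$output_shape, collapse = "x"),
              paste(x$margin, collapse = "/")))
  invisible(x)
}

#' Is an input shape admissible for a U-Net configuration?
#'
#' True iff symbolic shape propagation succeeds: every intermediate size
#' stays positive, every pre-pool size is divisible by the pool factor, and
#' every skip-connection crop margin splits evenly.
#'
#' @param config a [unet_config].
#' @param input_shape integer triple (or scalar).
#' @return logical.
#' @export
is_admissible_input <- function(config, input_shape) {
  if (length(input_shape) == 1L) input_shape <- rep(input_shape, 3L)
  all(vapply(input_shape,
             function(n) n >= 1 && !is.null(propagate_axis(config, as.integer(n))),
             logical(1)))
}

# internal: nearest admissible per-axis size (for error messages)
nearest_admissible <- function(config, n, search = 64L) {
  n <- as.integer(n)
  for (d in 0:search) {
    for (cand in unique(c(n + d, n - d))) {
      if (cand >= 1L && !is.null(propagate_axis(config, cand))) return(cand)
    }
  }
  NA_integer_
}
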