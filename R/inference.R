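#' Plan sliding windows over a volume
#'
#' Per axis, window corners start at 0 with stride
#' `floor(patch * (1 - overlap))`; when the last regular window would
#' overrun, a final corner clamped to `volume - patch` is appended. Windows
#' are half-open and together cover the whole volume.
#'
#' @param volume_shape integer triple.
#' @param patch_size integer triple (or scalar).
#' @param overlap overlap fraction in `[0, 1)` (reference protocol: 0.5).
#' @return a `sliding_window_plan`: list with `corners` (N x 3 matrix of
#'   0-based corners), `patch_size`, `volume_shape`, `overlap` and `padded`
#'   (TRUE when the patch exceeds the volume along some axis, in which case
#'   a single padding window is planned).
#' @export
plan_sliding_windows <- function(volume_shape, patch_size, overlap = 0.5) {
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  volume_shape <- as.integer(rep(volume_shape, length.out = 3L))
  patch_size <- as.integer(rep(patch_size, length.out = 3L))
  padded <- any(patch_size > volume_shape)
  axis_corners <- lapply(1:3, function(a) {
    p <- patch_size[a]; v <- volume_shape[a]
    if (p >= v) return(0L)
    stride <- max(1L, as.integer(floor(p * (1 - overlap))))
    cs <- seq.int(0L, v - p, by = stride)
    if (cs[length(cs)] != v - p) cs <- c(cs, v - p)
    as.integer(cs)
  })
  grid <- as.matrix(expand.grid(x = axis_corners[[1]], y = axis_corners[[2]],
                                z = axis_corners[[3]], KEEP.OUT.ATTRS = FALSE))
  structure(list(corners = unname(grid), patch_size = patch_size,
                 volume_shape = volume_shape, overlap = overlap, padded = padded),
            class = "sliding_window_plan")
}

#' @export
print.sliding_window_plan <- function(x, ...) {
  cat(sprintf("<sliding_window_plan: %d windows of %s over %s, overlap %.2f%s>\n",
              nrow(x$corners), paste(x$patch_size, collapse = "x"),
              paste(x$volume_shape, collapse = "x"), x$overlap,
              if (x$padded) ", padding required" else ""))
  invisible(x)
}

# internal: symmetric reflect padding of a 3D array by lo/hi voxels per axis
pad_reflect3 <- function(v, lo, hi) {
  idx <- lapply(1:3, function(a) {
    n <- dim(v)[a]
    left <- if (lo[a] > 0) rev(seq_len(min(lo[a], n))) else integer(0)
    while (length(left) < lo[a]) left <- c(left[1], left) # degenerate tiny axes
    right <- if (hi[a] > 0) n + 1L - seq_len(min(hi[a], n)) else integer(0)
    while (length(right) < hi[a]) right <- c(right, right[length(right)])
    c(left, seq_len(n), right)
  })
  v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# internal: run a patch through either a unet_model or a plain function
run_patch <- function(model, patch) {
  if (inherits(model, "unet_model")) forward_unet(model, patch)$out
  else model(patch)
}

#' Sliding-window prediction of a full volume
#'
#' Extracts overlapping patches, runs each through the network, stitches the
#' (smaller, centered) output footprints back and divides the aggregated
#' probabilities voxelwise by the number of contributing patches. Because
#' valid convolutions shrink each output, the volume is first reflect-padded
#' by the network margin (and up to the patch size if smaller than a patch),
#' so that every original voxel is covered by at least one output footprint.
#'
#' @param model a `unet_model`, or a function `patch -> output array`
#'   (outputs must be centered crops of their inputs by a fixed margin).
#' @param image intensity [volume_grid] (already normalized for the model).
#' @param patch_size input patch size (admissible for the model).
#' @param overlap overlap fraction (default 0.5).
#' @param plan optional precomputed [plan_sliding_windows()] over the padded
#'   volume; mainly for testing.
#' @return probability [volume_grid] with values in \[0,1\], same grid as
#'   `image`.
#' @export
predict_volume <- function(model, image, patch_size, overlap = 0.5, plan = NULL) {
  d <- dim(image)
  patch_size <- as.integer(rep(patch_size, length.out = 3L))
  if (inherits(model, "unet_model")) {
    tab <- compute_shape_table(model$config, patch_size) # errors if inadmissible
    margin <- tab$margin
  } else {
    probe <- run_patch(model, array(0, patch_size))
    margin <- (patch_size - dim(probe)) %/% 2L
  }
  lo <- margin
  hi <- margin + pmax(patch_size - (d + 2L * margin), 0L) # also pad tiny volumes
  padded <- pad_reflect3(vg_values(image), lo, hi)
  pd <- dim(padded)
  if (is.null(plan)) plan <- plan_sliding_windows(pd, patch_size, overlap)
  acc <- array(0, pd)
  cnt <- array(0, pd)
  out_size <- patch_size - 2L * margin
  for (w in seq_len(nrow(plan$corners))) {
    cr <- plan$corners[w, ]
    patch <- padded[cr[1] + seq_len(patch_size[1]),
                    cr[2] + seq_len(patch_size[2]),
                    cr[3] + seq_len(patch_size[3]), drop = FALSE]
    out <- run_patch(model, patch)
    ix <- cr[1] + margin[1] + seq_len(out_size[1])
    iy <- cr[2] + margin[2] + seq_len(out_size[2])
    iz <- cr[3] + margin[3] + seq_len(out_size[3])
    acc[ix, iy, iz] <- acc[ix, iy, iz] + out
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  covered <- cnt > 0
  acc[covered] <- acc[covered] / cnt[covered]
  res <- acc[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3]),
             drop = FALSE]
  vg_like(res, image)
}

#' Rule-based extraction of the final airway tree
#'
#' The four post-processing steps: (1) mask the probability map to the lung
#' fields, (2) binarize at `threshold` (0.5 by default; 0.1 in EXACT mode),
#' (3) merge with the central-airway (trachea + main bronchi) mask, and
#' (4) keep the largest connected component at the requested connectivity
#' (26 by default; 6 in EXACT mode). Ties between equal-size components
#' keep the one containing a central-mask voxel, else the one whose first
#' voxel comes first in scan order.
#'
#' @param prob probability [volume_grid].
#' @param lung_mask binary lung-field mask.
#' @param central_mask binary trachea/main-bronchi mask (or NULL).
#' @param threshold binarization threshold in (0,1).
#' @param connectivity 26 or 6.
#' @return binary [volume_grid]: a single connected component (or empty,
#'   with a warning).
#' @export
extract_airway_tree <- function(prob, lung_mask, central_mask = NULL,
                                threshold = 0.5, connectivity = 26L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  check_aligned(prob, lung_mask, central_mask, what = "extraction inputs")
  bin <- (unclass(prob) * (unclass(lung_mask) > 0)) >= threshold
  merged <- if (is.null(central_mask)) bin else bin | (unclass(central_mask) > 0)
  if (!any(merged)) {
    warning("empty segmentation after thresholding and merging")
    return(vg_like(array(0, dim(prob)), prob))
  }
  cc <- largest_component(array(as.numeric(merged), dim(prob)),
                          connectivity = connectivity,
                          prefer = if (is.null(central_mask)) NULL else unclass(central_mask))
  vg_like(cc, prob)
}
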