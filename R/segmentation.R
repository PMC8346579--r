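#' Simplified region-growing lung segmentation
#'
#' Thresholds air-like intensities, keeps connected components that do not
#' touch the lateral (x/y) image borders and exceed a minimum size, and
#' closes the result morphologically so thin airway walls inside the lung
#' are absorbed. A deliberately simple stand-in for a full clinical lung
#' segmentation; on phantoms it recovers the synthetic lung field.
#'
#' @param image intensity [volume_grid] in stored (HU-like) units.
#' @param air_threshold intensities below this count as air.
#' @param min_size smallest component kept, voxels.
#' @param closing_radius iterations of 6-neighbourhood closing.
#' @return binary [volume_grid]; empty (with a warning) when no air-like
#'   component is found.
#' @export
segment_lungs <- function(image, air_threshold = -600, min_size = 100L,
                          closing_radius = 2L) {
  v <- vg_values(image)
  air <- array(as.integer(v < air_threshold), dim(v))
  if (!any(air == 1L)) {
    warning("no air-like voxels below the threshold; returning an empty mask")
    return(vg_like(array(0, dim(v)), image))
  }
  lab <- .label_components(air, 6L)
  d <- dim(v)
  border_labels <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ]))
  sizes <- tabulate(lab)
  keep <- setdiff(which(sizes >= min_size), border_labels)
  if (length(keep) == 0L) {
    warning("no interior air component found; returning an empty mask")
    return(vg_like(array(0, dim(v)), image))
  }
  mask <- array(as.integer(lab %in% keep), d)
  if (closing_radius > 0) {
    mask <- .binary_morph(mask, as.integer(closing_radius), TRUE, 6L)
    mask <- .binary_morph(mask, as.integer(closing_radius), FALSE, 6L)
  }
  vg_like(array(as.numeric(mask), d), image)
}

#' Simplified region-growing trachea / main-bronchi segmentation
#'
#' Finds the most superior dark, roughly circular cross-section in the top
#' axial slices (or uses an explicit seed), then grows a 26-connected region
#' upper-bounded by an intensity threshold. The threshold is increased
#' stepwise with a volume-explosion guard: when a step multiplies the region
#' volume by more than `explode_factor` (or exceeds `max_frac` of the
#' volume), the previous threshold's region is returned.
#'
#' @param image intensity [volume_grid].
#' @param seed_point optional integer triple (1-based voxel index) forcing
#'   the growth seed.
#' @param seed_threshold intensity below which a voxel can seed the growth.
#' @param threshold_range candidate upper thresholds, tried in order.
#' @param explode_factor growth-ratio guard between consecutive thresholds.
#' @param max_frac absolute cap as a fraction of the volume.
#' @return binary [volume_grid], 26-connected by construction.
#' @export
segment_central_airways <- function(image, seed_point = NULL,
                                    seed_threshold = -900,
                                    threshold_range = seq(-950, -700, by = 25),
                                    explode_factor = 3,
                                    max_frac = 0.05) {
  v <- vg_values(image)
  d <- dim(v)
  if (is.null(seed_point)) {
    # scan from the top axial slice downwards for a dark cross-section
    for (z in rev(seq_len(d[3]))) {
      sl <- v[, , z]
      if (!any(sl < seed_threshold)) next
      sl3 <- array(as.integer(sl < seed_threshold), c(d[1], d[2], 1L))
      lab <- .label_components(sl3, 26L)
      sizes <- tabulate(lab)
      k <- which.max(sizes)
      if (sizes[k] < 5L) next
      idx <- which(lab[, , 1] == k, arr.ind = TRUE)
      ctr <- round(colMeans(idx))
      if (v[ctr[1], ctr[2], z] < seed_threshold) {
        seed_point <- c(ctr[1], ctr[2], z)
        break
      }
    }
    if (is.null(seed_point))
      stop("no dark tubular seed found in the top slices; ",
           "supply seed_point explicitly")
  }
  seed_point <- as.integer(seed_point)
  if (v[seed_point[1], seed_point[2], seed_point[3]] > max(threshold_range))
    stop("seed voxel is not air-like (intensity ",
         round(v[seed_point[1], seed_point[2], seed_point[3]]),
         "); supply a seed inside the airway lumen")
  seed_lin <- (seed_point[1] - 1L) +
    d[1] * ((seed_point[2] - 1L) + d[2] * (seed_point[3] - 1L))
  best <- NULL; best_n <- 0L
  for (thr in threshold_range) {
    grown <- .region_grow(v, seed_lin, -Inf, thr, 26L, max_frac)
    n <- sum(grown)
    if (n == 0L) next
    if (n > max_frac * prod(d) ||
        (best_n > 20L && n > explode_factor * best_n)) break
    best <- grown; best_n <- n
  }
  if (is.null(best))
    stop("region growing produced no region; supply a seed inside the lumen")
  vg_like(array(as.numeric(best), d), image)
}
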