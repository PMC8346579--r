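#' Configuration for the synthetic airway phantom
#'
#' The phantom emulates the structures a CT airway segmentation method
#' relies on: a branching tube tree with per-generation decreasing radii,
#' a dark lumen enclosed by a brighter wall, dark noisy parenchyma inside a
#' lung field surrounded by soft tissue, optional bright vessel-like tubes,
#' and exact ground-truth lumen, centerline, lung and root (trachea-analogue)
#' masks. Intensities are abstract HU-like units.
#'
#' @param volume_shape integer triple, voxels.
#' @param spacing mm per voxel, all > 0.
#' @param n_generations number of tube generations including the root (>= 1).
#' @param root_radius lumen radius of the root tube, voxels.
#' @param radius_ratio per-generation radius multiplier in (0,1).
#' @param length_ratio per-generation length multiplier in (0,1).
#' @param root_length root tube length in voxels (default: 22% of the
#'   z-dimension).
#' @param branch_angle_deg mean bifurcation half-angle, degrees.
#' @param wall_thickness airway wall shell thickness, voxels (>= 0).
#' @param intensity_lumen,intensity_wall,intensity_parenchyma,intensity_vessel
#'   painted intensities; the lumen must be darker than the wall.
#' @param intensity_body soft-tissue intensity outside the lung field.
#' @param noise_sigma additive Gaussian noise standard deviation (>= 0).
#' @param n_vessels number of bright vessel-like tubes (>= 0).
#' @param seed integer seed; identical config and seed give a bit-identical
#'   phantom.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(volume_shape = c(64, 64, 64),
                           spacing = c(0.7, 0.7, 1.0),
                           n_generations = 4L,
                           root_radius = 4,
                           radius_ratio = 0.75,
                           length_ratio = 0.8,
                           root_length = NULL,
                           branch_angle_deg = 35,
                           wall_thickness = 1.5,
                           intensity_lumen = -1000,
                           intensity_wall = -200,
                           intensity_parenchyma = -850,
                           intensity_vessel = 50,
                           intensity_body = -200,
                           noise_sigma = 25,
                           n_vessels = 6L,
                           seed = 1L) {
  cfg <- list(volume_shape = as.integer(volume_shape), spacing = as.numeric(spacing),
              n_generations = as.integer(n_generations), root_radius = root_radius,
              radius_ratio = radius_ratio, length_ratio = length_ratio,
              root_length = root_length %||% round(0.22 * volume_shape[3]),
              branch_angle_deg = branch_angle_deg, wall_thickness = wall_thickness,
              intensity_lumen = intensity_lumen, intensity_wall = intensity_wall,
              intensity_parenchyma = intensity_parenchyma,
              intensity_vessel = intensity_vessel, intensity_body = intensity_body,
              noise_sigma = noise_sigma, n_vessels = as.integer(n_vessels),
              seed = as.integer(seed))
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 8L))
    stop("volume_shape must be three integers >= 8")
  if (any(cfg$spacing <= 0)) stop("spacing must be positive")
  if (cfg$n_generations < 1L) stop("n_generations must be >= 1")
  if (cfg$root_radius <= 0) stop("root_radius must be > 0")
  if (cfg$radius_ratio <= 0 || cfg$radius_ratio >= 1)
    stop("radius_ratio must lie in (0,1)")
  if (cfg$length_ratio <= 0 || cfg$length_ratio >= 1)
    stop("length_ratio must lie in (0,1)")
  if (cfg$wall_thickness < 0) stop("wall_thickness must be >= 0")
  if (cfg$intensity_lumen >= cfg$intensity_wall)
    stop("the lumen must be darker than the wall (intensity_lumen < intensity_wall)")
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (cfg$n_vessels < 0) stop("n_vessels must be >= 0")
  class(cfg) <- "phantom_config"
  cfg
}

#' Generate the branching-tube skeleton of a phantom
#'
#' Builds a connected binary tree of straight tube segments rooted at a
#' trachea-analogue oriented along the superior-inferior (z) axis, entering
#' from the top slice. Radii follow `root_radius * radius_ratio^generation`
#' exactly; bifurcation angles and azimuths are jittered by the seeded random
#' source. All segments, dilated by their outer radius, fit inside the volume.
#'
#' @param config a [phantom_config].
#' @return a data.frame with one row per segment: `sx,sy,sz` (start point),
#'   `ex,ey,ez` (end point, continuous 0-based voxel coordinates), `radius`,
#'   `wall`, `parent` (row index of the parent, NA for the root) and
#'   `generation` (0 for the root).
#' @export
generate_tree_skeleton <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$volume_shape
  margin <- config$root_radius + config$wall_thickness + 1.5
  if (any(dims < 2 * margin) || config$root_length + margin >= dims[3])
    stop("invalid config: volume too small to contain the root segment")
  with_local_seed(derive_seed(config$seed, "skeleton"), {
    rows <- list()
    root_start <- c(dims[1] / 2, dims[2] / 2, dims[3] - 1)
    root_dir <- c(0, 0, -1)
    root_end <- root_start + config$root_length * root_dir
    rows[[1]] <- data.frame(sx = root_start[1], sy = root_start[2], sz = root_start[3],
                            ex = root_end[1], ey = root_end[2], ez = root_end[3],
                            radius = config$root_radius, wall = config$wall_thickness,
                            parent = NA_integer_, generation = 0L)
    frontier <- list(list(index = 1L, dir = root_dir, len = config$root_length))
    for (g in seq_len(config$n_generations - 1L)) {
      radius <- max(1.0, config$root_radius * config$radius_ratio^g)
      nxt <- list()
      for (node in frontier) {
        parent_row <- rows[[node$index]]
        start <- c(parent_row$ex, parent_row$ey, parent_row$ez)
        d <- node$dir
        # branching plane: toward the two lungs at the carina, random deeper
        if (g == 1L) {
          e1 <- c(1, 0, 0)
        } else {
          phi <- runif(1, 0, 2 * pi)
          # orthonormal vector perpendicular to d
          ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
          u <- ref - sum(ref * d) * d; u <- u / sqrt(sum(u^2))
          v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
                 d[1] * u[2] - d[2] * u[1])
          e1 <- cos(phi) * u + sin(phi) * v
        }
        e1 <- e1 - sum(e1 * d) * d
        e1 <- e1 / sqrt(sum(e1^2))
        for (side in c(-1, 1)) {
          theta <- (config$branch_angle_deg + runif(1, -8, 8)) * pi / 180
          cd <- cos(theta) * d + side * sin(theta) * e1
          cd <- cd / sqrt(sum(cd^2))
          len <- node$len * config$length_ratio * runif(1, 0.9, 1.1)
          m <- radius + config$wall_thickness + 1.5
          # shorten so the capsule stays inside the volume
          tmax <- len
          for (ax in 1:3) {
            if (cd[ax] > 1e-9)  tmax <- min(tmax, (dims[ax] - 1 - m - start[ax]) / cd[ax])
            if (cd[ax] < -1e-9) tmax <- min(tmax, (m - start[ax]) / cd[ax])
          }
          if (tmax < 3) { # points out of the volume: fold back toward centre
            centre <- dims / 2
            for (ax in 1:3) if ((centre[ax] - start[ax]) * cd[ax] < 0) cd[ax] <- -cd[ax]
            cd <- cd / sqrt(sum(cd^2))
            tmax <- len
            for (ax in 1:3) {
              if (cd[ax] > 1e-9)  tmax <- min(tmax, (dims[ax] - 1 - m - start[ax]) / cd[ax])
              if (cd[ax] < -1e-9) tmax <- min(tmax, (m - start[ax]) / cd[ax])
            }
          }
          len <- max(2, min(len, tmax))
          endp <- start + len * cd
          rows[[length(rows) + 1L]] <-
            data.frame(sx = start[1], sy = start[2], sz = start[3],
                       ex = endp[1], ey = endp[2], ez = endp[3],
                       radius = radius, wall = config$wall_thickness,
                       parent = node$index, generation = g)
          nxt[[length(nxt) + 1L]] <- list(index = length(rows), dir = cd, len = len)
        }
      }
      frontier <- nxt
    }
    do.call(rbind, rows)
  })
}

# internal: rasterize capsules for a subset of segment rows, radii offset by
# `grow` voxels
capsules_of <- function(segments, dims, grow = 0) {
  .rasterize_capsules(as.matrix(segments[, c("sx", "sy", "sz")]),
                      as.matrix(segments[, c("ex", "ey", "ez")]),
                      pmax(segments$radius + grow, 0.01), as.integer(dims))
}

# internal: binary ellipsoid
ellipsoid_mask <- function(dims, centre, semi) {
  x <- (seq_len(dims[1]) - 1 - centre[1]) / semi[1]
  y <- (seq_len(dims[2]) - 1 - centre[2]) / semi[2]
  z <- (seq_len(dims[3]) - 1 - centre[3]) / semi[3]
  q <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(as.integer(q <= 1), dims)
}

#' Rasterize a tube tree into an airway phantom
#'
#' Paints the skeleton into voxel grids: the lumen is the union of capsules
#' (cylinders with spherical caps) of each segment's radius; the wall is the
#' shell between the lumen and the capsule grown by `wall_thickness`. The
#' lung field is one or two ellipsoids enclosing all non-root segments with
#' the (dilated) root capsule removed, so the trachea analogue is excluded
#' from the region of interest. The exterior is painted at soft-tissue
#' intensity, optional bright vessel-like tubes are added inside the lung,
#' and seeded Gaussian noise is applied.
#'
#' @param segments a segment table from [generate_tree_skeleton()].
#' @param config the [phantom_config] the segments were generated from.
#' @return an `airway_phantom`: list with [volume_grid]s `image`,
#'   `lumen_mask`, `centerline_mask`, `lung_mask`, `root_mask`, plus the
#'   `segments` table and `config`.
#' @export
rasterize_phantom <- function(segments, config) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1)
  dims <- config$volume_shape
  wall_t <- config$wall_thickness
  lumen <- capsules_of(segments, dims)
  outer_caps <- capsules_of(segments, dims, grow = wall_t)
  wall_mask <- outer_caps == 1L & lumen == 0L

  root <- segments[is.na(segments$parent), , drop = FALSE]
  nonroot <- segments[!is.na(segments$parent), , drop = FALSE]
  # subtracted from the lung field un-dilated: the lung must stop exactly at
  # the trachea analogue so the central mask stays adjacent to the in-lung
  # tree and the merged segmentation remains a single connected component
  root_capsule <- capsules_of(root, dims)

  # lung field: ellipsoids around the two first-generation subtrees
  lung <- array(0L, dims)
  if (nrow(nonroot) > 0) {
    side_of <- function(seg_rows) { # assign each segment to a gen-1 ancestor
      anc <- integer(nrow(segments))
      for (i in seq_len(nrow(segments))) {
        j <- i
        while (!is.na(segments$parent[j]) && segments$generation[j] > 1L) j <- segments$parent[j]
        anc[i] <- j
      }
      anc
    }
    anc <- side_of(segments)
    gen1 <- which(segments$generation == 1L)
    groups <- if (length(gen1) == 2L && min(dims[1:2]) >= 48L)
      list(which(anc == gen1[1]), which(anc == gen1[2])) else list(which(segments$generation >= 1L))
    for (grp in groups) {
      pts <- rbind(as.matrix(segments[grp, c("sx", "sy", "sz")]),
                   as.matrix(segments[grp, c("ex", "ey", "ez")]))
      lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
      centre <- (lo + hi) / 2
      semi_max <- pmax(pmin(centre - 1.5, dims - 1 - centre - 1.5), 3) # stay off borders
      semi <- pmax((hi - lo) / 2 + config$root_radius + wall_t + 3, 6)
      semi <- pmin(semi, semi_max)
      ell <- ellipsoid_mask(dims, centre, semi)
      # inflate until the ellipsoid encloses this subtree's lumen
      for (it in 1:4) {
        uncovered <- capsules_of(segments[grp, , drop = FALSE], dims) == 1L & ell == 0L &
          root_capsule == 0L
        if (!any(uncovered)) break
        semi <- pmin(semi * 1.2, semi_max)
        ell <- ellipsoid_mask(dims, centre, semi)
      }
      lung <- lung | ell
    }
  } else {
    centre <- c(dims[1] / 4, dims[2] / 2, dims[3] / 2)
    lung <- ellipsoid_mask(dims, centre, pmax(dims / 5, 4))
  }
  lung_mask <- array(as.numeric(lung & root_capsule == 0L), dims)
  root_mask <- array(as.numeric(root_capsule == 1L & lung_mask == 0), dims)

  # centerline from the generative axes (exact reference, not thinning)
  centerline <- array(0, dims)
  for (i in seq_len(nrow(segments))) {
    a <- as.numeric(segments[i, c("sx", "sy", "sz")])
    b <- as.numeric(segments[i, c("ex", "ey", "ez")])
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / 0.3)))
    vox <- unique(round(t(a + t(outer(ts, b - a)))))
    vox <- vox[vox[, 1] >= 0 & vox[, 1] < dims[1] &
               vox[, 2] >= 0 & vox[, 2] < dims[2] &
               vox[, 3] >= 0 & vox[, 3] < dims[3], , drop = FALSE]
    centerline[vox + 1L] <- 1
  }
  centerline <- centerline * (lumen == 1L)

  img <- array(config$intensity_body, dims)
  img[lung_mask == 1] <- config$intensity_parenchyma

  with_local_seed(derive_seed(config$seed, "texture"), {
    if (config$n_vessels > 0 && nrow(nonroot) > 0) {
      bbox_lo <- pmax(apply(as.matrix(nonroot[, c("sx", "sy", "sz")]), 2, min) - 4, 2)
      bbox_hi <- pmin(apply(as.matrix(nonroot[, c("ex", "ey", "ez")]), 2, max) + 4, dims - 3)
      vs <- ve <- matrix(0, config$n_vessels, 3)
      vr <- numeric(config$n_vessels)
      for (k in seq_len(config$n_vessels)) {
        vs[k, ] <- runif(3, bbox_lo, bbox_hi)
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        ve[k, ] <- pmin(pmax(vs[k, ] + dir * runif(1, 0.15, 0.3) * dims[1], 2), dims - 3)
        vr[k] <- runif(1, 1, 2.5)
      }
      vessels <- .rasterize_capsules(vs, ve, vr, as.integer(dims))
      img[vessels == 1L & outer_caps == 0L] <- config$intensity_vessel
    }
    img[wall_mask] <- config$intensity_wall
    img[lumen == 1L] <- config$intensity_lumen
    if (config$noise_sigma > 0)
      img <- img + array(rnorm(prod(dims), 0, config$noise_sigma), dims)
  })

  structure(list(image = volume_grid(img, config$spacing),
                 lumen_mask = volume_grid(array(as.numeric(lumen == 1L), dims), config$spacing),
                 centerline_mask = volume_grid(centerline, config$spacing),
                 lung_mask = volume_grid(lung_mask, config$spacing),
                 root_mask = volume_grid(root_mask, config$spacing),
                 segments = segments, config = config),
            class = "airway_phantom")
}

#' Generate a complete airway phantom
#'
#' Convenience wrapper: [generate_tree_skeleton()] followed by
#' [rasterize_phantom()]. Deterministic given `config` (including its seed).
#'
#' @param config a [phantom_config].
#' @return an `airway_phantom`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  rasterize_phantom(generate_tree_skeleton(config), config)
}

#' Generate a set of phantoms with varied seeds
#'
#' @param n number of phantoms.
#' @param config base [phantom_config]; each phantom gets a seed derived from
#'   `seed` and its index.
#' @param seed base seed for the set.
#' @return list of `airway_phantom` objects.
#' @export
generate_phantom_set <- function(n, config = phantom_config(), seed = 1L) {
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, "phantom", i)
    generate_phantom(cfg)
  })
}

#' @export
print.airway_phantom <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<airway_phantom %dx%dx%d, %d segments, %d generations, seed %d>\n",
              d[1], d[2], d[3], nrow(x$segments),
              max(x$segments$generation) + 1L, x$config$seed))
  cat(sprintf("  lumen %d vox | centerline %d vox | lung %d vox | root %d vox\n",
              sum(x$lumen_mask > 0), sum(x$centerline_mask > 0),
              sum(x$lung_mask > 0), sum(x$root_mask > 0)))
  invisible(x)
}

#' Write a phantom to disk as NIfTI volumes plus a YAML manifest
#'
#' @param phantom an `airway_phantom`.
#' @param dir output directory (created if needed).
#' @param name basename prefix for the five volumes.
#' @return the manifest path, invisibly.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(image = "image", lumen_mask = "lumen", centerline_mask = "centerline",
                lung_mask = "lungs", root_mask = "root")
  files <- list()
  for (field in names(paths)) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", name, paths[[field]]))
    write_volume(phantom[[field]], f)
    files[[field]] <- basename(f)
  }
  manifest <- file.path(dir, paste0(name, "_manifest.yaml"))
  yaml::write_yaml(list(config = unclass(phantom$config), files = files), manifest)
  invisible(manifest)
}
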