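#' Construct a volume grid
#'
#' A volume grid is the package's common geometric substrate: a 3D numeric
#' array with a voxel spacing attribute (mm per voxel along each axis). By
#' role it holds intensities, probabilities in \[0,1\], or binary masks in
#' \{0,1\}; the same container is used for all three.
#'
#' @param values 3D numeric, integer or logical array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @return an object of class `volume_grid` (a 3D array with a `spacing`
#'   attribute).
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1)) {
  if (length(dim(values)) != 3L)
    stop("volume_grid requires a 3D array, got dimensions: ",
         paste(dim(values), collapse = "x"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers")
  # rebuild as a bare double array: drops any foreign attributes (e.g. the
  # internal handles RNifti attaches) so grids compare by value
  values <- array(as.double(values), dim(values))
  structure(values, spacing = spacing, class = c("volume_grid", "array"))
}

#' Voxel spacing of a volume grid
#' @param x a `volume_grid` or plain array.
#' @return numeric length-3 spacing in mm (1,1,1 for plain arrays).
#' @export
voxel_spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) c(1, 1, 1) else s
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x)
  s <- voxel_spacing(x)
  u <- sort(unique(as.vector(x)))
  role <- if (length(u) <= 2 && all(u %in% c(0, 1))) "binary"
          else if (min(x) >= 0 && max(x) <= 1) "probability/intensity [0,1]"
          else "intensity"
  cat(sprintf("<volume_grid %dx%dx%d, spacing %.3gx%.3gx%.3g mm, %s, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], s[1], s[2], s[3], role, min(x), max(x)))
  invisible(x)
}

# internal: coerce to plain double array, keep dims
vg_values <- function(x) {
  v <- unclass(x)
  attr(v, "spacing") <- NULL
  storage.mode(v) <- "double"
  v
}

# internal: integer {0,1} array for the C++ kernels
vg_binary <- function(x) {
  v <- unclass(x)
  attr(v, "spacing") <- NULL
  b <- array(as.integer(v != 0), dim(v))
  b
}

# internal: wrap an array with the spacing of a template grid
vg_like <- function(values, template) volume_grid(values, voxel_spacing(template))

# internal: check that grids share shape (and spacing, when both carry one)
check_aligned <- function(..., what = "grids") {
  gs <- list(...)
  gs <- gs[!vapply(gs, is.null, logical(1))]
  d0 <- dim(gs[[1]])
  for (g in gs[-1]) {
    if (!identical(dim(g), d0))
      stop(what, " are not aligned: shapes ",
           paste(d0, collapse = "x"), " vs ", paste(dim(g), collapse = "x"))
  }
  invisible(TRUE)
}

# internal: largest connected component, deterministic tie-break.
# Ties keep the component containing a voxel of `prefer` (binary array), else
# the component whose first (lowest linear index) voxel comes first.
largest_component <- function(mask, connectivity = 26L, prefer = NULL) {
  lab <- .label_components(vg_binary(mask), as.integer(connectivity))
  if (!any(lab > 0L)) return(array(0, dim(mask)))
  sizes <- tabulate(lab)
  mx <- max(sizes)
  cand <- which(sizes == mx)
  pick <- cand[1]
  if (length(cand) > 1L && !is.null(prefer)) {
    pv <- as.vector(prefer) != 0
    for (k in cand) if (any(lab[pv] == k)) { pick <- k; break }
  }
  array(as.numeric(lab == pick), dim(mask))
}
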