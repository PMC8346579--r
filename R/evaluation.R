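#' Skeletonize a binary mask
#'
#' 3D medial-axis thinning: topology-preserving directional border peeling
#' (simple-point deletion with endpoint preservation) down to a unit-width,
#' per-component 26-connected centerline contained in the input mask.
#'
#' @param mask binary [volume_grid] or 3D array.
#' @return binary [volume_grid] skeleton.
#' @export
skeletonize_mask <- function(mask) {
  sk <- .skeletonize3d(vg_binary(mask))
  out <- array(as.numeric(sk), dim(mask))
  if (inherits(mask, "volume_grid")) vg_like(out, mask) else volume_grid(out)
}

#' Remove the central airways from evaluation inputs
#'
#' Dilates the exclusion mask by `dilate` voxels (26-neighbourhood, to absorb
#' boundary voxels) and zeroes it out of the prediction, the ground truth and
#' any centerlines, mirroring the convention that the trachea and main
#' bronchi do not count in the airway metrics.
#'
#' @param inputs named list with `pred`, `truth`, and optionally
#'   `centerline` (ground-truth centerline) and `pred_centerline`.
#' @param exclusion binary mask of the central airways (or NULL: no-op).
#' @param dilate dilation iterations applied to the exclusion mask.
#' @return the list with masked grids.
#' @export
exclude_central_airways <- function(inputs, exclusion, dilate = 1L) {
  if (is.null(exclusion) || !any(unclass(exclusion) > 0)) return(inputs)
  check_aligned(inputs$pred, exclusion, what = "exclusion inputs")
  ex <- if (dilate > 0)
    .binary_morph(vg_binary(exclusion), as.integer(dilate), TRUE, 26L)
  else vg_binary(exclusion)
  keep <- array(as.numeric(ex == 0L), dim(ex))
  for (nm in intersect(names(inputs), c("pred", "truth", "centerline", "pred_centerline"))) {
    if (!is.null(inputs[[nm]]))
      inputs[[nm]] <- vg_like(unclass(inputs[[nm]]) * keep, inputs[[nm]])
  }
  inputs
}

#' Tree length detected (percent)
#'
#' Percentage of ground-truth centerline voxels lying inside the prediction
#' mask: a completeness measure.
#'
#' @param pred binary prediction mask.
#' @param truth_centerline binary ground-truth centerline (non-empty).
#' @return percent in \[0, 100\].
#' @export
tree_length_detected <- function(pred, truth_centerline) {
  check_aligned(pred, truth_centerline)
  n <- sum(unclass(truth_centerline) > 0)
  if (n == 0) stop("tree length undefined: empty ground-truth centerline")
  100 * sum(unclass(truth_centerline) > 0 & unclass(pred) > 0) / n
}

#' Centerline leakage (percent)
#'
#' Predicted-centerline voxels outside the ground-truth mask, as a
#' percentage of the ground-truth centerline length: a specificity measure.
#'
#' @param pred_centerline binary predicted centerline.
#' @param truth binary ground-truth mask.
#' @param truth_centerline_length reference length (voxels, > 0).
#' @return percent (unbounded above).
#' @export
centerline_leakage <- function(pred_centerline, truth, truth_centerline_length) {
  check_aligned(pred_centerline, truth)
  if (truth_centerline_length <= 0)
    stop("centerline leakage undefined: zero reference centerline length")
  100 * sum(unclass(pred_centerline) > 0 & unclass(truth) == 0) / truth_centerline_length
}

#' False positive rate (percent)
#'
#' Predicted voxels outside the ground truth as a percentage of the
#' ground-truth voxel count. Not clamped: can exceed 100.
#'
#' @param pred binary prediction mask.
#' @param truth binary ground-truth mask (non-empty).
#' @return percent.
#' @export
false_positive_rate <- function(pred, truth) {
  check_aligned(pred, truth)
  n <- sum(unclass(truth) > 0)
  if (n == 0) stop("false positive rate undefined: empty ground truth")
  100 * sum(unclass(pred) > 0 & unclass(truth) == 0) / n
}

#' Dice overlap coefficient
#'
#' `2|P inter G| / (|P| + |G|)`; defined as 1 when both masks are empty.
#'
#' @param pred,truth binary masks.
#' @return scalar in \[0, 1\].
#' @export
dice_coefficient <- function(pred, truth) {
  check_aligned(pred, truth)
  p <- unclass(pred) > 0; g <- unclass(truth) > 0
  denom <- sum(p) + sum(g)
  if (denom == 0) return(1)
  2 * sum(p & g) / denom
}

#' Total detected tree length (mm)
#'
#' Number of ground-truth centerline voxels inside the prediction times the
#' geometric mean of the voxel sizes in the three dimensions.
#'
#' @param pred binary prediction mask.
#' @param truth_centerline binary ground-truth centerline.
#' @param spacing voxel spacing in mm (default: the grids' spacing).
#' @return length in mm.
#' @export
total_tree_length <- function(pred, truth_centerline, spacing = NULL) {
  check_aligned(pred, truth_centerline)
  spacing <- spacing %||% voxel_spacing(truth_centerline)
  if (any(spacing <= 0)) stop("spacing must be positive")
  sum(unclass(truth_centerline) > 0 & unclass(pred) > 0) * prod(spacing)^(1 / 3)
}

#' Evaluate an airway prediction against ground truth
#'
#' Composes the full evaluation: central-airway exclusion (with 1-voxel
#' dilation), skeletonization of the prediction and — when no generative
#' centerline is supplied — of the ground truth, then all five metrics.
#'
#' @param pred binary prediction [volume_grid].
#' @param truth binary ground-truth mask.
#' @param truth_centerline optional exact ground-truth centerline; computed
#'   by [skeletonize_mask()] when absent.
#' @param exclusion optional central-airway (trachea + main bronchi) mask.
#' @param spacing voxel spacing in mm (default: from the grids).
#' @param exclusion_dilate dilation applied to the exclusion mask.
#' @return an `airway_eval`: list with `tree_length_pct`,
#'   `centerline_leakage_pct`, `false_positive_rate_pct`, `dice`,
#'   `total_tree_length_mm`.
#' @export
evaluate_airway <- function(pred, truth, truth_centerline = NULL,
                            exclusion = NULL, spacing = NULL,
                            exclusion_dilate = 1L) {
  check_aligned(pred, truth, truth_centerline, exclusion, what = "evaluation grids")
  spacing <- spacing %||% voxel_spacing(truth)
  inputs <- list(pred = pred, truth = truth, centerline = truth_centerline)
  inputs <- exclude_central_airways(inputs, exclusion, exclusion_dilate)
  if (is.null(inputs$centerline))
    inputs$centerline <- skeletonize_mask(inputs$truth)
  pred_cl <- skeletonize_mask(inputs$pred)
  res <- list(
    tree_length_pct = tree_length_detected(inputs$pred, inputs$centerline),
    centerline_leakage_pct = centerline_leakage(
      pred_cl, inputs$truth, sum(unclass(inputs$centerline) > 0)),
    false_positive_rate_pct = false_positive_rate(inputs$pred, inputs$truth),
    dice = dice_coefficient(inputs$pred, inputs$truth),
    total_tree_length_mm = total_tree_length(inputs$pred, inputs$centerline, spacing))
  class(res) <- "airway_eval"
  res
}

#' @export
print.airway_eval <- function(x, ...) {
  cat(sprintf(paste0("<airway_eval: TL %.1f%% | CL %.1f%% | FPR %.2f%% | ",
                     "DSC %.3f | total length %.1f mm>\n"),
              x$tree_length_pct, x$centerline_leakage_pct,
              x$false_positive_rate_pct, x$dice, x$total_tree_length_mm))
  invisible(x)
}

#' Batch evaluation to a data frame
#'
#' One row per case plus a summary row of medians and quartiles, matching
#' the usual reporting style for airway segmentation benchmarks.
#'
#' @param results named list of `airway_eval` objects.
#' @return a data.frame; the last row (`case == "median (IQR)"`-style rows
#'   `median`, `q25`, `q75`) summarizes the cases.
#' @export
eval_summary <- function(results) {
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(case = nm, TL = r$tree_length_pct, CL = r$centerline_leakage_pct,
               FPR = r$false_positive_rate_pct, DSC = r$dice,
               total_length_mm = r$total_tree_length_mm)
  }))
  num <- rows[, -1, drop = FALSE]
  summ <- function(f, nm) cbind(case = nm, as.data.frame(as.list(apply(num, 2, f))))
  rbind(rows,
        summ(median, "median"),
        summ(function(x) quantile(x, 0.25, names = FALSE), "q25"),
        summ(function(x) quantile(x, 0.75, names = FALSE), "q75"))
}
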