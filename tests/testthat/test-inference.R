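test_that("sliding-window plans tile the volume at the configured stride", {
  # degenerate: volume equals patch
  p1 <- plan_sliding_windows(c(32, 32, 32), 32, 0.5)
  expect_equal(nrow(p1$corners), 1L)
  expect_equal(p1$corners[1, ], c(0L, 0L, 0L))
  # volume twice the patch, 50% overlap: corners {0, p/2, p} per axis
  p2 <- plan_sliding_windows(c(32, 32, 32), 16, 0.5)
  expect_equal(nrow(p2$corners), 27L)
  expect_setequal(unique(p2$corners[, 1]), c(0L, 8L, 16L))
  # brute-force coverage over random shapes
  set.seed(21)
  for (i in 1:100) {
    vs <- sample(10:40, 3, replace = TRUE)
    ps <- pmin(vs, sample(5:20, 3, replace = TRUE))
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    plan <- plan_sliding_windows(vs, ps, ov)
    covered <- array(0L, vs)
    for (w in seq_len(nrow(plan$corners))) {
      cr <- plan$corners[w, ]
      covered[cr[1] + seq_len(ps[1]), cr[2] + seq_len(ps[2]),
              cr[3] + seq_len(ps[3])] <- covered[cr[1] + seq_len(ps[1]),
                                                 cr[2] + seq_len(ps[2]),
                                                 cr[3] + seq_len(ps[3])] + 1L
    }
    expect_true(all(covered >= 1L)) # full coverage, count >= 1 everywhere
    strides <- diff(sort(unique(plan$corners[, 1])))
    if (length(strides) > 1)
      expect_true(all(head(strides, -1) == max(1L, floor(ps[1] * (1 - ov)))))
  }
})

test_that("overlap-averaged stitching reproduces constant and copying stubs", {
  img <- volume_grid(array(rnorm(40 * 36 * 30), c(40, 36, 30)))
  margin <- 4L
  const_model <- function(patch) {
    d <- dim(patch) - 2L * margin
    array(0.37, d)
  }
  out <- predict_volume(const_model, img, patch_size = c(20, 20, 20))
  expect_equal(as.vector(out), rep(0.37, length(img)), tolerance = 1e-12)
  # a stub that emits the centered crop of its input reproduces the image
  copy_model <- function(patch) {
    d <- dim(patch)
    patch[(margin + 1):(d[1] - margin), (margin + 1):(d[2] - margin),
          (margin + 1):(d[3] - margin)]
  }
  out2 <- predict_volume(copy_model, img, patch_size = c(20, 20, 20))
  expect_equal(unclass(out2), unclass(img), tolerance = 1e-12,
               ignore_attr = TRUE)
  # patch larger than the volume: reflect-pad, predict, crop back
  small <- volume_grid(array(rnorm(12^3), c(12, 12, 12)))
  out3 <- predict_volume(copy_model, small, patch_size = c(20, 20, 20))
  expect_equal(unclass(out3), unclass(small), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("aggregation is idempotent in the overlap fraction for a real model", {
  # a pool-free (single-level, valid) network is exactly shift-equivariant,
  # so differently overlapping plans must average to the same map; pooled
  # networks are only equivariant to shifts that are multiples of the total
  # pooling factor, which generic window strides do not respect
  cfg <- unet_config(n_levels = 1, n_features_first = 2, n_valid_levels = 1,
                     init_seed = 19)
  model <- build_unet(cfg)
  set.seed(4)
  img <- volume_grid(array(runif(36^3), c(36, 36, 36)))
  a <- predict_volume(model, img, patch_size = c(20, 20, 20), overlap = 0.5)
  b <- predict_volume(model, img, patch_size = c(20, 20, 20), overlap = 0.75)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-5)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("airway extraction follows the mask-threshold-merge-component rules", {
  dims <- c(30, 30, 30)
  lung <- array(1, dims)
  # probability zero everywhere: output is the largest component of the
  # central mask
  central <- array(0, dims)
  central[5:8, 5:8, 5:8] <- 1   # 64 voxels
  central[20:21, 20:21, 20:21] <- 1 # 8 voxels
  out <- extract_airway_tree(volume_grid(array(0, dims)), volume_grid(lung),
                             volume_grid(central))
  expect_equal(sum(out), 64)
  expect_equal(sum(out[5:8, 5:8, 5:8]), 64)
  # two disconnected lung components, no central mask: larger one survives
  prob <- array(0, dims)
  prob[2:6, 2:5, 2:6] <- 1   # 100 voxels
  prob[20:24, 20:23, 20:21] <- 1 # 40 voxels
  out2 <- extract_airway_tree(volume_grid(prob), volume_grid(lung), NULL, 0.5)
  expect_equal(sum(out2), 100)
  # probability mass outside the lung mask can never appear in the output
  lung2 <- array(0, dims); lung2[1:15, , ] <- 1
  prob2 <- array(1, dims)
  out3 <- extract_airway_tree(volume_grid(prob2), volume_grid(lung2), NULL)
  expect_equal(sum(out3[16:30, , ]), 0)
  # lowering the threshold never removes voxels from the thresholded mask
  set.seed(2)
  pr <- array(runif(prod(dims)), dims)
  hi <- (pr * lung2) >= 0.5
  lo <- (pr * lung2) >= 0.1
  expect_true(all(lo[hi]))
  # the final mask is one connected component at the requested connectivity
  for (conn in c(26L, 6L)) {
    res <- extract_airway_tree(volume_grid(pr), volume_grid(lung2), NULL,
                               threshold = 0.97, connectivity = conn)
    if (sum(res) > 0) {
      lab <- airwaynet:::.label_components(airwaynet:::vg_binary(res), conn)
      expect_equal(max(lab), 1L)
    }
  }
})

test_that("the lung stub recovers the synthetic lung field", {
  ph <- generate_phantom(tiny_phantom_config(seed = 8))
  lungs <- segment_lungs(ph$image)
  expect_true(all(unclass(lungs) %in% c(0, 1)))
  expect_identical(dim(lungs), dim(ph$image))
  expect_gte(dice_coefficient(lungs, ph$lung_mask), 0.9)
  # uniformly bright volume: nothing below the air threshold
  bright <- volume_grid(array(100, c(20, 20, 20)))
  expect_warning(empty <- segment_lungs(bright), "empty")
  expect_equal(sum(empty), 0)
})

test_that("the central-airway stub grows from the trachea analogue", {
  ph <- generate_phantom(tiny_phantom_config(seed = 12))
  central <- segment_central_airways(ph$image)
  frac <- sum(central > 0 & ph$root_mask > 0) / sum(ph$root_mask > 0)
  expect_gte(frac, 0.95)
  lab <- airwaynet:::.label_components(airwaynet:::vg_binary(central), 26L)
  expect_equal(max(lab), 1L) # region growing yields one 26-connected region
  # a seed inside a bright region violates the precondition
  expect_error(segment_central_airways(ph$image, seed_point = c(2, 2, 2)),
               "not air-like")
})
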