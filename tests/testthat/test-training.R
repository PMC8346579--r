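make_sample <- function(dims = c(40, 40, 40), roi_lo = 11, roi_hi = 30, seed = 1) {
  set.seed(seed)
  hi <- pmin(roi_hi, dims - 2)
  img <- volume_grid(array(runif(prod(dims)), dims))
  roi <- array(0, dims)
  roi[roi_lo:hi[1], roi_lo:hi[2], roi_lo:hi[3]] <- 1
  lab <- array(0, dims)
  lab[(roi_lo + 2):(hi[1] - 2), (roi_lo + 2):(hi[2] - 2), roi_lo:hi[3]] <- 1
  airway_sample(img, volume_grid(lab), volume_grid(roi), id = paste0("s", seed))
}

test_that("ROI bounding-box crop applies buffer, clamping and label masking", {
  # ROI occupies voxels 41..80 (0-based [40,80)) in a 128^3 volume
  dims <- c(128, 128, 128)
  roi <- array(0, dims); roi[41:80, 41:80, 41:80] <- 1
  lab <- array(0, dims)
  lab[45:70, 45:70, 45:70] <- 1
  lab[10:20, 10:20, 10:20] <- 1 # outside the ROI: must vanish
  s <- airway_sample(volume_grid(array(0, dims)), volume_grid(lab),
                     volume_grid(roi), "a")
  cropped <- crop_to_roi_bbox(s, 30)
  expect_identical(dim(cropped$image), c(100L, 100L, 100L)) # [10,110) per axis
  expect_equal(sum(cropped$labels), 26^3) # out-of-ROI labels removed
  # ROI touching the border clamps at the volume limits
  roi2 <- array(0, dims); roi2[1:10, 41:80, 41:80] <- 1
  s2 <- airway_sample(s$image, s$labels, volume_grid(roi2), "b")
  expect_identical(dim(crop_to_roi_bbox(s2, 30)$image), c(40L, 100L, 100L))
  expect_error(crop_to_roi_bbox(
    airway_sample(s$image, s$labels, volume_grid(array(0, dims)), "c")), "empty")
})

test_that("patch corners are uniform over the admissible range", {
  s <- make_sample(c(30, 26, 24))
  # degenerate: sample equals patch -> corner pinned at the origin
  pp <- sample_random_patch(s, c(30, 26, 24))
  expect_equal(pp$corner, c(0L, 0L, 0L))
  set.seed(99)
  corners <- t(replicate(1000, sample_random_patch(s, c(20, 20, 20))$corner))
  expect_identical(dim(sample_random_patch(s, c(20, 20, 20))$image_patch),
                   c(20L, 20L, 20L))
  ranges <- c(10, 6, 4) # D-d per axis
  for (a in 1:3) {
    expect_gte(min(corners[, a]), 0)
    expect_lte(max(corners[, a]), ranges[a])
    # empirical mean within 3 standard errors of the uniform midpoint
    se <- sqrt(((ranges[a] + 1)^2 - 1) / 12) / sqrt(1000)
    expect_lt(abs(mean(corners[, a]) - ranges[a] / 2), 3 * se)
    # goodness-of-fit against the discrete uniform at alpha = 0.01
    obs <- tabulate(corners[, a] + 1, nbins = ranges[a] + 1)
    expect_gt(stats::chisq.test(obs)$p.value, 0.01)
  }
  expect_error(sample_random_patch(s, c(40, 20, 20)), "exceeds")
})

test_that("augmentation is the identity at null parameters and flips are involutions", {
  s <- make_sample()
  set.seed(3)
  pp <- sample_random_patch(s, c(24, 24, 24))
  ident <- apply_rigid(pp, flips = c(FALSE, FALSE, FALSE),
                       angles_deg = c(0, 0, 0), scale = 1)
  expect_equal(unclass(ident$image_patch), unclass(pp$image_patch), tolerance = 1e-12)
  expect_identical(unclass(ident$label_patch), unclass(pp$label_patch))
  disabled <- augment_patch(pp, augment_config(enabled = FALSE))
  expect_identical(disabled, pp)
  for (fl in list(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, TRUE))) {
    once <- apply_rigid(pp, flips = fl)
    twice <- apply_rigid(once, flips = fl)
    expect_equal(unclass(twice$image_patch), unclass(pp$image_patch), tolerance = 1e-12)
    expect_identical(unclass(twice$roi_patch), unclass(pp$roi_patch))
  }
})

test_that("nearest-neighbour resampling keeps labels binary across random draws", {
  s <- make_sample(c(28, 28, 28), roi_lo = 6, roi_hi = 24)
  cfg <- augment_config()
  set.seed(11)
  for (i in 1:40) {
    pp <- augment_patch(sample_random_patch(s, c(20, 20, 20)), cfg)
    expect_true(all(unclass(pp$label_patch) %in% c(0, 1)))
    expect_true(all(unclass(pp$roi_patch) %in% c(0, 1)))
    expect_identical(dim(pp$image_patch), c(20L, 20L, 20L))
  }
})

test_that("soft Dice loss satisfies its identities and hand-computed value", {
  dims <- c(8, 8, 8)
  g <- random_binary(dims, 0.4)
  roi <- array(1, dims)
  expect_equal(masked_soft_dice_loss(g, g, roi), 0, tolerance = 1e-5)
  expect_equal(masked_soft_dice_loss(array(0, dims), g, roi), 1, tolerance = 1e-5)
  # ROI of 8 voxels, p = 0.5 everywhere, 4 positives: 1 - 2*2/(4+4) = 0.5
  roi2 <- array(0, dims); roi2[1:2, 1:2, 1:2] <- 1
  g2 <- array(0, dims); g2[1:2, 1:2, 1] <- 1
  expect_equal(masked_soft_dice_loss(array(0.5, dims), g2, roi2), 0.5,
               tolerance = 1e-6)
  # bounds over random inputs
  set.seed(5)
  for (i in 1:20) {
    l <- masked_soft_dice_loss(array(runif(prod(dims)), dims),
                               random_binary(dims, runif(1)),
                               random_binary(dims, 0.7))
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("voxels outside the ROI influence neither the loss nor its gradient", {
  set.seed(8)
  dims <- c(10, 10, 10)
  p <- array(runif(prod(dims)), dims)
  g <- random_binary(dims, 0.3)
  roi <- random_binary(dims, 0.5)
  base <- airwaynet:::soft_dice_loss_grad(p, g, roi)
  p2 <- p; g2 <- g
  out <- which(roi == 0)
  p2[out] <- runif(length(out)); g2[out] <- rbinom(length(out), 1, 0.5)
  pert <- airwaynet:::soft_dice_loss_grad(p2, g2, roi)
  expect_identical(base$loss, pert$loss)
  expect_identical(base$grad[roi > 0], pert$grad[roi > 0])
  expect_true(all(base$grad[roi == 0] == 0))
})

test_that("convergence rule stops on stall and rise but not on steady descent", {
  cfg <- train_config(ma_window_epochs = 5, stop_patience_epochs = 4)
  hist <- function(v) list(val_loss = v)
  # never stops before window + patience epochs
  expect_false(convergence_check(hist(rep(1, 8)), cfg)$stop)
  # steady geometric descent (1% per epoch) never stops
  dec <- 0.99^(0:59)
  for (n in 9:60) expect_false(convergence_check(hist(dec[1:n]), cfg)$stop)
  # constant loss stalls as soon as the rule is armed
  cc <- convergence_check(hist(rep(0.5, 9)), cfg)
  expect_true(cc$stop); expect_equal(cc$reason, "stall")
  # hand-built series whose moving average rises 6% across the patience gap
  v <- c(rep(0.50, 5), rep(0.54, 4))
  ma_then <- mean(v[1:5]); ma_now <- mean(v[5:9])
  stopifnot(ma_now / ma_then > 1.05)
  cc2 <- convergence_check(hist(v), cfg)
  expect_true(cc2$stop); expect_equal(cc2$reason, "rise")
})

test_that("zero learning rate leaves weights unchanged; fixed seeds reproduce runs", {
  samples <- list(make_sample(seed = 1), make_sample(seed = 2),
                  make_sample(seed = 3))
  ucfg <- tiny_unet_config(seed = 4)
  tcfg <- train_config(learning_rate = 0, patch_size = c(20, 20, 20),
                       max_epochs = 2, ma_window_epochs = 2,
                       stop_patience_epochs = 1, val_fraction = 0.34, seed = 9)
  model <- build_unet(ucfg)
  fit0 <- train_unet(model, samples, tcfg, augment_config(enabled = FALSE))
  expect_identical(fit0$model$params, model$params)
  expect_equal(fit0$history$val_loss[1], fit0$history$val_loss[2])

  tcfg$learning_rate <- 1e-3
  fit1 <- train_unet(model, samples, tcfg, augment_config())
  fit2 <- train_unet(model, samples, tcfg, augment_config())
  expect_identical(fit1$history$train_loss, fit2$history$train_loss)
  expect_identical(fit1$history$val_loss, fit2$history$val_loss)
  expect_identical(fit1$model$params, fit2$model$params)
})

test_that("a few epochs of optimization reduce the training loss", {
  set.seed(31)
  samples <- lapply(1:3, function(i) make_sample(c(26, 26, 26), 4, 24, seed = i))
  tcfg <- train_config(learning_rate = 1e-3, patch_size = c(20, 20, 20),
                       patches_per_scan_per_epoch = 4, max_epochs = 6,
                       ma_window_epochs = 6, stop_patience_epochs = 2,
                       val_fraction = 0.34, seed = 2)
  fit <- train_unet(build_unet(tiny_unet_config(seed = 1)), samples, tcfg,
                    augment_config(enabled = FALSE))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_equal(fit$history$best_epoch, which.min(fit$history$val_loss))
})

test_that("an inadmissible patch size is rejected up front", {
  samples <- list(make_sample(seed = 1), make_sample(seed = 2))
  expect_error(
    train_unet(build_unet(tiny_unet_config()), samples,
               train_config(patch_size = c(21, 21, 21), max_epochs = 1)),
    "not admissible")
})
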