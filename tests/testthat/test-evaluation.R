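test_that("each metric reproduces its hand-counted example", {
  dims <- c(16, 16, 16)
  # tree length: 10 centerline voxels, 7 inside the prediction
  Gc <- array(0, dims); Gc[3:12, 8, 8] <- 1
  P <- array(0, dims); P[3:9, 6:10, 6:10] <- 1
  expect_equal(tree_length_detected(volume_grid(P), volume_grid(Gc)), 70)
  expect_equal(tree_length_detected(volume_grid(array(1, dims)), volume_grid(Gc)), 100)
  expect_equal(tree_length_detected(volume_grid(array(0, dims)), volume_grid(Gc)), 0)
  expect_error(tree_length_detected(volume_grid(P), volume_grid(array(0, dims))),
               "empty")
  # leakage: 5 predicted-centerline voxels outside G, reference length 50
  G <- array(0, dims); G[1:8, , ] <- 1
  Pc <- array(0, dims); Pc[4:13, 4, 4] <- 1 # 5 in, 5 out
  expect_equal(centerline_leakage(volume_grid(Pc), volume_grid(G), 50), 10)
  expect_equal(centerline_leakage(volume_grid(G), volume_grid(G), 50), 0)
  expect_error(centerline_leakage(volume_grid(Pc), volume_grid(G), 0), "zero")
  # FPR: |G| = 300, 30 predicted voxels outside
  G2 <- array(0, dims); G2[1:3, 1:10, 1:10] <- 1
  P2 <- G2; P2[5, 1:5, 1:6] <- 1
  expect_equal(false_positive_rate(volume_grid(P2), volume_grid(G2)), 10)
  expect_equal(false_positive_rate(volume_grid(G2), volume_grid(G2)), 0)
  # FPR is unbounded above
  P3 <- array(0, dims); P3[10:16, 1:10, 1:10] <- 1
  expect_gt(false_positive_rate(volume_grid(P3), volume_grid(G2)), 100)
  # Dice: |P|=6, |G|=2, overlap 2 -> 0.5
  Pd <- array(0, dims); Pd[1:6, 1, 1] <- 1
  Gd <- array(0, dims); Gd[1:2, 1, 1] <- 1
  expect_equal(dice_coefficient(volume_grid(Pd), volume_grid(Gd)), 0.5)
  expect_equal(dice_coefficient(volume_grid(Gd), volume_grid(Gd)), 1)
  expect_equal(dice_coefficient(volume_grid(array(0, dims)),
                                volume_grid(array(0, dims))), 1)
  # total tree length with anisotropic spacing: 100 * (0.5*0.5*1)^(1/3)
  Gc2 <- array(0, dims); Gc2[1:10, 1:10, 1] <- 1
  expect_equal(total_tree_length(volume_grid(array(1, dims)), volume_grid(Gc2),
                                 c(0.5, 0.5, 1.0)),
               100 * 0.25^(1 / 3))
  expect_equal(total_tree_length(volume_grid(array(0, dims)), volume_grid(Gc2),
                                 c(1, 1, 1)), 0)
})

test_that("metrics agree exactly with brute-force per-voxel oracles", {
  set.seed(77)
  for (i in 1:20) {
    dims <- sample(8:32, 3, replace = TRUE)
    P <- random_binary(dims, runif(1, 0.1, 0.5))
    G <- random_binary(dims, runif(1, 0.1, 0.5))
    Gc <- G * random_binary(dims, 0.3)
    if (sum(Gc) == 0 || sum(G) == 0) next
    o <- oracle_metrics(P, G, Gc, spacing = c(0.6, 0.6, 1.1))
    expect_identical(tree_length_detected(volume_grid(P), volume_grid(Gc)), o$tl)
    expect_identical(false_positive_rate(volume_grid(P), volume_grid(G)), o$fpr)
    expect_identical(dice_coefficient(volume_grid(P), volume_grid(G)), o$dice)
    expect_identical(total_tree_length(volume_grid(P), volume_grid(Gc),
                                       c(0.6, 0.6, 1.1)), o$total_len)
    Pc <- P * random_binary(dims, 0.2)
    expect_identical(centerline_leakage(volume_grid(Pc), volume_grid(G), sum(Gc)),
                     oracle_leakage(Pc, G, sum(Gc)))
  }
})

test_that("percentages are spacing-invariant and length scales with spacing", {
  ph <- generate_phantom(tiny_phantom_config(seed = 14))
  P <- ph$lumen_mask
  ev1 <- evaluate_airway(P, ph$lumen_mask, ph$centerline_mask,
                         exclusion = ph$root_mask, spacing = c(1, 1, 1))
  ev2 <- evaluate_airway(P, ph$lumen_mask, ph$centerline_mask,
                         exclusion = ph$root_mask, spacing = c(2, 2, 2))
  expect_equal(ev1$tree_length_pct, ev2$tree_length_pct)
  expect_equal(ev1$dice, ev2$dice)
  expect_equal(ev2$total_tree_length_mm, 2 * ev1$total_tree_length_mm)
})

test_that("skeletonization thins a tube to (roughly) its axis, inside the mask", {
  expect_equal(sum(skeletonize_mask(volume_grid(array(0, c(8, 8, 8))))), 0)
  tube <- array(0, c(20, 20, 50))
  for (z in 5:45) {
    sl <- outer((1:20 - 10)^2, (1:20 - 10)^2, `+`) <= 9
    tube[, , z][sl] <- 1
  }
  sk <- skeletonize_mask(volume_grid(tube))
  expect_true(all(tube[unclass(sk) > 0] == 1))
  axis_len <- 41
  expect_lt(abs(sum(sk) - axis_len) / axis_len, 0.2)
  # containment holds across random phantoms
  for (s in 1:3) {
    ph <- generate_phantom(tiny_phantom_config(seed = 30 + s))
    sk <- skeletonize_mask(ph$lumen_mask)
    expect_equal(sum(unclass(sk) > 0 & unclass(ph$lumen_mask) == 0), 0)
  }
})

test_that("central-airway exclusion removes the root and shields the metrics", {
  ph <- generate_phantom(tiny_phantom_config(seed = 16))
  inputs <- list(pred = ph$lumen_mask, truth = ph$lumen_mask,
                 centerline = ph$centerline_mask)
  # empty exclusion mask: inputs unchanged
  same <- exclude_central_airways(inputs, volume_grid(array(0, dim(ph$image))))
  expect_identical(unclass(same$pred), unclass(inputs$pred))
  # prediction equal to the exclusion mask vanishes
  gone <- exclude_central_airways(list(pred = ph$root_mask, truth = ph$lumen_mask),
                                  ph$root_mask)
  expect_equal(sum(gone$pred), 0)
  # after exclusion no ground-truth centerline voxel remains in the root
  ex <- exclude_central_airways(inputs, ph$root_mask)
  expect_equal(sum(unclass(ex$centerline) > 0 & unclass(ph$root_mask) > 0), 0)
  # metrics are blind to arbitrary changes strictly inside the dilated mask
  dil <- airwaynet:::.binary_morph(airwaynet:::vg_binary(ph$root_mask), 1L, TRUE, 26L)
  ev_a <- evaluate_airway(ph$lumen_mask, ph$lumen_mask, ph$centerline_mask,
                          exclusion = ph$root_mask)
  P2 <- unclass(ph$lumen_mask); G2 <- unclass(ph$lumen_mask)
  set.seed(3)
  inside <- which(dil == 1L)
  P2[inside] <- rbinom(length(inside), 1, 0.5)
  G2[inside] <- rbinom(length(inside), 1, 0.5)
  ev_b <- evaluate_airway(volume_grid(P2, voxel_spacing(ph$image)),
                          volume_grid(G2, voxel_spacing(ph$image)),
                          ph$centerline_mask, exclusion = ph$root_mask)
  expect_equal(ev_a$tree_length_pct, ev_b$tree_length_pct)
  expect_equal(ev_a$false_positive_rate_pct, ev_b$false_positive_rate_pct)
  expect_equal(ev_a$dice, ev_b$dice)
})

test_that("composed evaluation handles partial trees and spurs as expected", {
  ph <- generate_phantom(tiny_phantom_config(seed = 18))
  # deleting the deepest generation lowers TL but leaks nothing
  segs <- ph$segments
  deep <- segs$generation == max(segs$generation)
  partial_mask <- airwaynet:::capsules_of(segs[!deep, , drop = FALSE],
                                          dim(ph$image))
  partial <- volume_grid(array(as.numeric(partial_mask == 1 &
                                            unclass(ph$lumen_mask) > 0),
                               dim(ph$image)), voxel_spacing(ph$image))
  ev <- evaluate_airway(partial, ph$lumen_mask, ph$centerline_mask,
                        exclusion = ph$root_mask)
  expect_lt(ev$tree_length_pct, 100)
  expect_gt(ev$tree_length_pct, 20)
  expect_equal(ev$centerline_leakage_pct, 0)
  # an 80-voxel spur outside a |G|=800 truth gives FPR 10
  dims <- c(24, 24, 24)
  G <- array(0, dims); G[3:10, 3:12, 3:12] <- 1 # 800 voxels
  P <- G; P[15:18, 15:18, 15:19] <- 1 # spur of 80
  Gc <- array(0, dims); Gc[3:10, 7, 7] <- 1
  ev2 <- evaluate_airway(volume_grid(P), volume_grid(G), volume_grid(Gc))
  expect_equal(ev2$false_positive_rate_pct, 10)
})

test_that("dice is symmetric and the batch summary reports quartiles", {
  set.seed(9)
  dims <- c(12, 12, 12)
  for (i in 1:5) {
    P <- volume_grid(random_binary(dims, 0.3))
    G <- volume_grid(random_binary(dims, 0.3))
    expect_identical(dice_coefficient(P, G), dice_coefficient(G, P))
  }
  ph <- generate_phantom(tiny_phantom_config(seed = 19))
  res <- list(a = evaluate_airway(ph$lumen_mask, ph$lumen_mask,
                                  ph$centerline_mask, ph$root_mask))
  df <- eval_summary(res)
  expect_equal(nrow(df), 4L) # case + median + q25 + q75
  expect_equal(df$DSC[df$case == "median"], 1)
})
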