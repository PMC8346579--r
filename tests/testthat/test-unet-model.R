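test_that("realized forward-pass shapes equal the shape-table prediction", {
  set.seed(7)
  tried <- 0
  while (tried < 5) {
    levels <- sample(2:3, 1)
    cfg <- unet_config(n_levels = levels, n_features_first = sample(1:3, 1),
                       n_valid_levels = sample(0:levels, 1),
                       convs_per_level = sample(1:2, 1),
                       init_seed = sample(1e4, 1))
    n <- sample(12:36, 1)
    if (!is_admissible_input(cfg, n)) next
    tried <- tried + 1
    model <- build_unet(cfg)
    out <- forward_unet(model, array(rnorm(n^3), rep(n, 3)))$out
    expect_identical(dim(out), compute_shape_table(cfg, n)$output_shape)
    expect_true(all(out >= 0 & out <= 1)) # sigmoid range
  }
})

test_that("forward pass is deterministic and zero final weights give 0.5", {
  cfg <- tiny_unet_config(seed = 11)
  model <- build_unet(cfg)
  x <- array(rnorm(20^3), c(20, 20, 20))
  expect_identical(forward_unet(model, x)$out, forward_unet(model, x)$out)
  model$params[["final.w"]][] <- 0
  model$params[["final.b"]][] <- 0
  expect_equal(as.vector(forward_unet(model, x)$out),
               rep(0.5, prod(compute_shape_table(cfg, 20)$output_shape)))
})

test_that("parameter count matches the closed-form layer bookkeeping", {
  # degenerate 1-level net: conv(1->F) + conv(F->F) + final 1x1x1 (F->1)
  F1 <- 3L
  cfg <- unet_config(n_levels = 1, n_features_first = F1, n_valid_levels = 1)
  hand <- (1 * 27 * F1 + F1) + (F1 * 27 * F1 + F1) + (F1 + 1)
  expect_equal(n_params(build_unet(cfg)), hand)

  # capacity grows strictly with the first-level feature count
  counts <- vapply(1:4, function(f)
    n_params(build_unet(unet_config(n_levels = 3, n_features_first = f))),
    numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  cfg <- tiny_unet_config(seed = 3)
  n <- 16
  model <- build_unet(cfg)
  x <- array(runif(n^3), rep(n, 3))
  os <- compute_shape_table(cfg, n)$output_shape
  g <- random_binary(os, 0.3)
  roi <- random_binary(os, 0.8)
  fw <- forward_unet(model, x, want_cache = TRUE)
  lg <- airwaynet:::soft_dice_loss_grad(fw$out, g, roi)
  gz <- array(lg$grad * fw$out * (1 - fw$out), c(dim(fw$out), 1))
  grads <- airwaynet:::backward_unet(model, fw$cache, gz)
  lossfun <- function(m) masked_soft_dice_loss(forward_unet(m, x)$out, g, roi)
  eps <- 1e-6
  for (nm in names(model$params)) {
    i <- sample(length(model$params[[nm]]), 1)
    up <- model; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- model; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    num <- (lossfun(up) - lossfun(dn)) / (2 * eps)
    # relative agreement with an absolute floor: central differences carry
    # O(1e-5) noise where a ReLU pre-activation sits within eps of zero
    expect_lt(abs(grads[[nm]][i] - num), max(2e-5, 0.02 * abs(num)),
              label = paste("gradient mismatch for", nm))
  }
})

test_that("a purely valid network is translation-consistent at the interior", {
  cfg <- unet_config(n_levels = 2, n_features_first = 2, n_valid_levels = 2,
                     init_seed = 13)
  shift <- 2 # pool_factor^(n_levels-1)
  n <- 24
  stopifnot(is_admissible_input(cfg, n), is_admissible_input(cfg, n + shift))
  model <- build_unet(cfg)
  set.seed(1)
  big <- array(rnorm((n + shift)^3), rep(n + shift, 3))
  out_a <- forward_unet(model, big[1:n, 1:n, 1:n])$out
  out_b <- forward_unet(model, big[shift + 1:n, shift + 1:n, shift + 1:n])$out
  os <- dim(out_a)[1]
  ov <- os - shift # overlapping output support
  expect_equal(out_a[shift + 1:ov, shift + 1:ov, shift + 1:ov],
               out_b[1:ov, 1:ov, 1:ov], tolerance = 1e-10)
})

test_that("checkpoints are self-describing and round-trip", {
  cfg <- tiny_unet_config(seed = 21)
  model <- build_unet(cfg)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(model, f, meta = list(epoch = 3))
  back <- load_checkpoint(f)
  expect_equal(back$config$n_levels, cfg$n_levels)
  expect_identical(back$params, model$params)
  expect_equal(attr(back, "meta")$epoch, 3)
  x <- array(rnorm(14^3), c(14, 14, 14))
  expect_identical(forward_unet(model, x)$out, forward_unet(back, x)$out)
})
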