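# Independent oracles used by the tests. These are deliberately written as
# naive, direct implementations (explicit loops, step-by-step size algebra)
# so they share no code path with the package internals they check.

# Symbolic shape propagation for one axis of the hybrid-padding U-Net,
# written as an explicit list of operations (conv/pool walk down, upsample/
# conv walk up with crop bookkeeping). Returns NA when inadmissible.
oracle_output_size <- function(n, levels, valid, k = 3, pool = 2, convs = 2) {
  enc <- integer(0)
  s <- n
  for (l in seq_len(levels)) {
    for (j in seq_len(convs)) if (l <= valid) s <- s - (k - 1)
    if (s < 1) return(NA_integer_)
    enc[l] <- s
    if (l < levels) {
      if (s %% pool != 0) return(NA_integer_)
      s <- s / pool
    }
  }
  for (l in rev(seq_len(levels - 1))) {
    s <- s * pool
    if (enc[l] - s < 0 || (enc[l] - s) %% 2 != 0) return(NA_integer_)
    for (j in seq_len(convs)) if (l <= valid) s <- s - (k - 1)
    if (s < 1) return(NA_integer_)
  }
  if ((n - s) %% 2 != 0) return(NA_integer_)
  as.integer(s)
}

# Brute-force per-voxel metric oracles: explicit triple loops, no set algebra.
oracle_metrics <- function(P, G, Gc, spacing = c(1, 1, 1)) {
  d <- dim(P)
  tp_cl <- n_cl <- fp <- ng <- np <- inter <- pcl_out <- 0
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    p <- P[x, y, z] > 0; g <- G[x, y, z] > 0; gc <- Gc[x, y, z] > 0
    if (gc) { n_cl <- n_cl + 1; if (p) tp_cl <- tp_cl + 1 }
    if (p && !g) fp <- fp + 1
    if (g) ng <- ng + 1
    if (p) np <- np + 1
    if (p && g) inter <- inter + 1
  }
  list(tl = 100 * tp_cl / n_cl,
       fpr = 100 * fp / ng,
       dice = if (np + ng == 0) 1 else 2 * inter / (np + ng),
       total_len = tp_cl * (spacing[1] * spacing[2] * spacing[3])^(1 / 3))
}

oracle_leakage <- function(Pc, G, ref_len) {
  d <- dim(Pc)
  out <- 0
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1]))
    if (Pc[x, y, z] > 0 && G[x, y, z] == 0) out <- out + 1
  100 * out / ref_len
}

# Small, fast phantom configuration used across tests
tiny_phantom_config <- function(seed = 1L, ...) {
  phantom_config(volume_shape = c(48, 48, 48), n_generations = 3L,
                 root_radius = 3.5, root_length = 11, n_vessels = 2L,
                 noise_sigma = 20, seed = seed, ...)
}

# Tiny admissible U-Net + matching training config for fast optimization tests
tiny_unet_config <- function(seed = 1L)
  unet_config(n_levels = 2L, n_features_first = 2L, n_valid_levels = 1L,
              init_seed = seed)

random_binary <- function(dims, p = 0.2) array(rbinom(prod(dims), 1, p), dims)
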