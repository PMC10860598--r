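# Shared small fixtures. A single-rep design (108 trials, 9 runs) keeps
# cross-validation cheap while preserving exact counterbalancing.

small_design <- function(seed = 7, jitter = TRUE) {
  build_design(seed = seed, reps = 1L,
               jitter_range = if (jitter) c(0, 10) else c(0, 0))
}

# config for a clean single-item (PMI-only) location signal
single_item_config <- function(n_voxels = 24L, noise_sd = 0, seed = 5L, ...) {
  on <- rep(1, 12)
  off <- rep(0, 12)
  synth_config(
    n_voxels = n_voxels, noise_sd = noise_sd, weight_noise_sd = 0,
    amp_profile = list(location = list(pmi = on, umi = off),
                       orientation = list(pmi = off, umi = off)),
    load_effect = list(content = off, context = off),
    seed = seed, ...
  )
}

# equal-amplitude two-item config (PMI and UMI driven identically)
equal_amp_config <- function(n_voxels = 32L, noise_sd = 0, seed = 5L, ...) {
  eq <- default_amp_profile()$location$pmi
  synth_config(
    n_voxels = n_voxels, noise_sd = noise_sd, weight_noise_sd = 0,
    amp_profile = list(location = list(pmi = eq, umi = eq),
                       orientation = list(pmi = eq, umi = eq)),
    load_effect = list(content = rep(0, 12), context = rep(0, 12)),
    seed = seed, ...
  )
}

# independent circular signed difference (oracle, deliberately not the
# package's wrap_signed)
circ_diff_oracle <- function(a, b, period) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}
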