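#' Default priority amplitude profiles
#'
#' Per-TR multiplicative gains on the channel signal of the prioritized (PMI)
#' and unprioritized (UMI) item, one profile per feature dimension, over the
#' 12 trial-locked 2-s TRs. The defaults emulate haemodynamically smoothed
#' epoch gains: both items rise after sample onset and are equal until the
#' first retrocue's effect arrives (~TR 7), after which the UMI is attenuated
#' while the PMI is maintained. They are illustrative regimes for testing the
#' pipeline, not fitted time courses.
#'
#' @return A list with elements `location` and `orientation`, each a list of
#'   numeric 12-vectors `pmi` and `umi`.
#' @export
default_amp_profile <- function() {
  rise <- c(0, 0.3, 0.8, 1, 1, 1)
  pmi <- c(rise, rep(1, 6))
  umi <- c(rise, 1, 0.8, 0.6, 0.5, 0.5, 0.5)
  list(location = list(pmi = pmi, umi = umi),
       orientation = list(pmi = pmi, umi = umi))
}

#' Default univariate load-effect profiles
#'
#' Additive ROI-wide signal increments (signal units per TR) applied on
#' load-of-2 trials relative to load-of-1 trials, separately for content
#' (location) load and context (orientation) load. Defaults mimic a region
#' whose activity is elevated by content load from the sample period onward
#' and by context load across the cue-to-late-delay window (TRs 7-10).
#'
#' @return A list with numeric 12-vectors `content` and `context`.
#' @export
default_load_effect <- function() {
  list(content = c(0, rep(0.3, 11)),
       context = c(rep(0, 6), rep(0.3, 4), 0, 0))
}

#' Synthetic-cohort configuration
#'
#' Bundles every knob of the synthetic BOLD generator: voxel count, additive
#' Gaussian noise, priority amplitude profiles, remapping regime, univariate
#' load effects, baseline intensity, and the coupling between neural and
#' behavioural load sensitivity.
#'
#' @param n_voxels Voxels per region (default 500, the size of the
#'   functionally selected regions in the task this emulates).
#' @param noise_sd SD of white Gaussian noise added per voxel/TR/trial,
#'   signal units.
#' @param amp_profile Per-TR PMI/UMI gains per dimension; see
#'   [default_amp_profile()].
#' @param remap_trs Integer TR indices (1-12) at which the UMI's channel
#'   vector is reflected about its mean before entering the voxel model
#'   (priority-based remapping regime); empty by default.
#' @param load_effect Additive load-of-2 gains per TR; see
#'   [default_load_effect()].
#' @param weight_noise_sd SD of Gaussian noise added to the voxel weight
#'   matrices (0 gives exactly basis-shaped voxel tuning).
#' @param baseline Constant baseline signal intensity added to every sample,
#'   so percent signal change against the run-mean intensity is well defined.
#' @param behavior_coupling Correlation rho in [-1, 1] linking a subject's
#'   neural load gain to their response-time load effect.
#' @param load_gain_sd SD of the subject-specific multiplicative load gain
#'   (mean 1) in cohort simulation.
#' @param rt_base,rt_scale Baseline mean RT (seconds) and the scale (seconds)
#'   of the standardized RT load effect in the behaviour table.
#' @param seed Integer seed making the generator reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_voxels = 500L, noise_sd = 1,
                         amp_profile = default_amp_profile(),
                         remap_trs = integer(0),
                         load_effect = default_load_effect(),
                         weight_noise_sd = 0.1, baseline = 100,
                         behavior_coupling = 0, load_gain_sd = 0.25,
                         rt_base = 1.1, rt_scale = 0.1,
                         seed = 1L) {
  stopifnot(n_voxels >= 1, noise_sd >= 0, weight_noise_sd >= 0)
  stopifnot(all(remap_trs %in% 1:12))
  stopifnot(abs(behavior_coupling) <= 1)
  for (dim in c("location", "orientation")) {
    stopifnot(length(amp_profile[[dim]]$pmi) == 12L,
              length(amp_profile[[dim]]$umi) == 12L)
  }
  stopifnot(length(load_effect$content) == 12L,
            length(load_effect$context) == 12L)
  structure(
    list(n_voxels = as.integer(n_voxels), noise_sd = noise_sd,
         amp_profile = amp_profile, remap_trs = as.integer(remap_trs),
         load_effect = load_effect, weight_noise_sd = weight_noise_sd,
         baseline = baseline, behavior_coupling = behavior_coupling,
         load_gain_sd = load_gain_sd, rt_base = rt_base, rt_scale = rt_scale,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Reflect a channel-response vector about its mean
#'
#' The remapping operation: maps a channel vector `c` to `2 * mean(c) - c`.
#' A center-peaked reconstruction becomes center-inverted while the channel
#' mean is preserved; applying the operation twice restores the input. This
#' is the generative counterpart of a negative reconstruction slope.
#'
#' @param c A numeric channel vector (length >= 2), or a k x n matrix whose
#'   columns are reflected independently.
#' @return An object of the same shape as `c`.
#' @export
#' @examples
#' remap_channel_vector(c(1, 0.5, 0, 0.5))
remap_channel_vector <- function(c) {
  if (is.matrix(c)) {
    stopifnot(nrow(c) >= 2)
    return(matrix(2 * colMeans(c), nrow(c), ncol(c), byrow = TRUE) - c)
  }
  stopifnot(length(c) >= 2)
  2 * mean(c) - c
}

#' Simulate one subject's BOLD dataset
#'
#' Generates a runs x voxels x TRs x trials-per-run block under a linear
#' encoding model: each voxel is assigned a preferred location and
#' orientation (uniform over the feature spaces) and its weight rows are the
#' basis activations of those preferences plus optional weight noise. Per
#' trial and TR the signal is the amplitude-weighted sum of the voxel's
#' response to the PMI and UMI features on both dimensions (with the UMI
#' channel vector reflected at `remap_trs`), plus the additive load effect,
#' the baseline intensity, and white Gaussian noise.
#'
#' @param design A `dsr_design` from [build_design()].
#' @param cfg A [synth_config()].
#' @return An object of class `bold_dataset`: list with `data` (array
#'   `n_runs x n_voxels x 12 x trials_per_run`), `design`, `zscored` flag and
#'   `truth` (weight matrices `W_loc`, `W_ori`, voxel preferences, and the
#'   generating config).
#' @export
simulate_subject <- function(design, cfg) {
  stopifnot(inherits(design, "dsr_design"), inherits(cfg, "synth_config"))
  loc_b <- location_basis()
  ori_b <- orientation_basis()
  if (cfg$n_voxels < max(loc_b$n_channels, ori_b$n_channels)) {
    stop("n_voxels (", cfg$n_voxels, ") must be at least the number of ",
         "channels (", max(loc_b$n_channels, ori_b$n_channels), ")")
  }
  set.seed(cfg$seed)
  v <- cfg$n_voxels
  n_trials <- nrow(design)
  n_runs <- max(design$run)
  tpr <- n_trials %/% n_runs

  pref_loc <- stats::runif(v, 0, 360)
  pref_ori <- stats::runif(v, 0, 180)
  W_loc <- t(ideal_channel_matrix(loc_b, pref_loc)) +
    matrix(stats::rnorm(v * loc_b$n_channels, 0, cfg$weight_noise_sd),
           v, loc_b$n_channels)
  W_ori <- t(ideal_channel_matrix(ori_b, pref_ori)) +
    matrix(stats::rnorm(v * ori_b$n_channels, 0, cfg$weight_noise_sd),
           v, ori_b$n_channels)

  feats <- item_features(design)
  Cp_loc <- ideal_channel_matrix(loc_b, feats$pmi_loc)
  Cu_loc <- ideal_channel_matrix(loc_b, feats$umi_loc)
  Cp_ori <- ideal_channel_matrix(ori_b, feats$pmi_ori)
  Cu_ori <- ideal_channel_matrix(ori_b, feats$umi_ori)
  Cu_loc_remap <- remap_channel_vector(Cu_loc)
  Cu_ori_remap <- remap_channel_vector(Cu_ori)

  loads <- load_assignment(design)
  load2_content <- as.numeric(loads$content_load == 2L)
  load2_context <- as.numeric(loads$context_load == 2L)

  ap <- cfg$amp_profile
  # voxel-by-trial signal components, computed once and rescaled per TR
  Mp_loc <- W_loc %*% Cp_loc
  Mu_loc <- W_loc %*% Cu_loc
  Mu_loc_r <- W_loc %*% Cu_loc_remap
  Mp_ori <- W_ori %*% Cp_ori
  Mu_ori <- W_ori %*% Cu_ori
  Mu_ori_r <- W_ori %*% Cu_ori_remap
  big <- array(0, dim = c(v, n_trials, 12L)) # voxel x trial x TR
  for (t in 1:12) {
    remap <- t %in% cfg$remap_trs
    S <- ap$location$pmi[t] * Mp_loc +
      ap$location$umi[t] * (if (remap) Mu_loc_r else Mu_loc) +
      ap$orientation$pmi[t] * Mp_ori +
      ap$orientation$umi[t] * (if (remap) Mu_ori_r else Mu_ori)
    load_t <- cfg$load_effect$content[t] * load2_content +
      cfg$load_effect$context[t] * load2_context
    big[, , t] <- S + rep(load_t, each = v) + cfg$baseline
  }
  if (cfg$noise_sd > 0) {
    big <- big + array(stats::rnorm(length(big), 0, cfg$noise_sd), dim(big))
  }
  arr <- array(0, dim = c(n_runs, v, 12L, tpr))
  for (r in seq_len(n_runs)) {
    arr[r, , , ] <- aperm(big[, design$run == r, , drop = FALSE], c(1, 3, 2))
  }
  structure(
    list(data = arr, design = design, zscored = FALSE,
         truth = list(W_loc = W_loc, W_ori = W_ori,
                      pref_loc = pref_loc, pref_ori = pref_ori,
                      config = cfg)),
    class = "bold_dataset"
  )
}

#' @export
print.bold_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_dataset> ", d[1], " runs x ", d[2], " voxels x ", d[3],
      " TRs x ", d[4], " trials/run", if (x$zscored) " (z-scored)", "\n",
      sep = "")
  invisible(x)
}

#' Extract the voxels-by-trials matrix at one TR
#'
#' @param dataset A `bold_dataset`.
#' @param tr TR index (1-12).
#' @param runs Runs to include (default all); columns are ordered by global
#'   trial index.
#' @return A `v x n_trials` matrix.
#' @export
get_tr_matrix <- function(dataset, tr, runs = NULL) {
  stopifnot(inherits(dataset, "bold_dataset"), tr %in% seq_len(dim(dataset$data)[3]))
  if (is.null(runs)) runs <- seq_len(dim(dataset$data)[1])
  mats <- lapply(runs, function(r) dataset$data[r, , tr, , drop = TRUE])
  do.call(cbind, mats)
}

#' Per-run preprocessing of a BOLD dataset
#'
#' `zscore_runs()` z-scores each voxel's samples within each run (across all
#' TRs and trials of the run), the standard preparation before encoding-model
#' estimation. `detrend_runs()` removes a polynomial trend of the given order
#' from each voxel's within-run sample sequence (ordered by trial, then TR);
#' on white-noise synthetic data this is a near no-op and is provided for
#' real-data ingestion.
#'
#' @param dataset A `bold_dataset`.
#' @param order Polynomial order 1-3 for `detrend_runs()`.
#' @return A `bold_dataset` with transformed `data` (and `zscored = TRUE`
#'   after z-scoring).
#' @export
zscore_runs <- function(dataset) {
  stopifnot(inherits(dataset, "bold_dataset"))
  d <- dataset$data
  n_runs <- dim(d)[1]
  v <- dim(d)[2]
  for (r in seq_len(n_runs)) {
    m <- matrix(d[r, , , ], nrow = v) # v x (TRs * trials)
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    sdv[sdv == 0] <- 1
    d[r, , , ] <- array((m - mu) / sdv, dim = dim(d)[-1])
  }
  dataset$data <- d
  dataset$zscored <- TRUE
  dataset
}

#' @rdname zscore_runs
#' @export
detrend_runs <- function(dataset, order = 1L) {
  stopifnot(inherits(dataset, "bold_dataset"), order %in% 1:3)
  d <- dataset$data
  n_runs <- dim(d)[1]
  v <- dim(d)[2]
  n_tr <- dim(d)[3]
  tpr <- dim(d)[4]
  # within-run sample order: trial-major, TR-minor (acquisition order)
  time <- as.vector(outer(seq_len(n_tr), seq_len(tpr),
                          function(t, j) (j - 1) * n_tr + t))
  X <- stats::poly(time, order)
  for (r in seq_len(n_runs)) {
    m <- matrix(d[r, , , ], nrow = v)
    fit <- stats::lm.fit(cbind(1, X), t(m))
    res <- sweep(fit$residuals, 2, rowMeans(m), "+") # keep each voxel's mean
    d[r, , , ] <- array(t(res), dim = dim(d)[-1])
  }
  dataset$data <- d
  dataset
}

#' Simulate a cohort with coupled behaviour
#'
#' Simulates `n_subjects` datasets sharing one trial schedule, with
#' subject-specific neural load gains `g_s ~ Normal(1, load_gain_sd)` scaling
#' the configured load-effect profiles, and a behaviour table whose per-subject
#' RT load effect is `rho * standardize(g_s) + sqrt(1 - rho^2) * noise`
#' (independently per load dimension), scaled by `rt_scale` seconds on top of
#' `rt_base`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param cfg A [synth_config()]; `cfg$seed` seeds the whole cohort.
#' @param design Optional shared `dsr_design`; built from `cfg$seed` if
#'   missing.
#' @return A list with `datasets` (list of `bold_dataset`), `behavior`
#'   (tibble: subject, dimension, load, rt), `truth` (tibble of subject load
#'   gains and RT effects) and `design`.
#' @export
simulate_cohort_with_behavior <- function(n_subjects, cfg, design = NULL) {
  stopifnot(n_subjects >= 2, inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  if (is.null(design)) design <- build_design(seed = cfg$seed)
  subj_seeds <- sample.int(.Machine$integer.max, n_subjects)
  g <- stats::rnorm(n_subjects, 1, cfg$load_gain_sd)
  gz <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0
  rho <- cfg$behavior_coupling
  rt_eff <- purrr::map(c(content = "content", context = "context"), function(d) {
    rho * gz + sqrt(1 - rho^2) * stats::rnorm(n_subjects)
  })

  datasets <- purrr::map(seq_len(n_subjects), function(s) {
    scfg <- cfg
    scfg$seed <- subj_seeds[s]
    scfg$load_effect <- purrr::map(cfg$load_effect, ~ .x * g[s])
    simulate_subject(design, scfg)
  })

  behavior <- tidyr::expand_grid(
    subject = seq_len(n_subjects),
    dimension = c("content", "context"),
    load = c(1L, 2L)
  )
  behavior$rt <- cfg$rt_base + ifelse(
    behavior$load == 2L,
    cfg$rt_scale * ifelse(behavior$dimension == "content",
                          rt_eff$content[behavior$subject],
                          rt_eff$context[behavior$subject]),
    0
  )
  truth <- tibble::tibble(subject = seq_len(n_subjects), load_gain = g,
                          rt_effect_content = rt_eff$content,
                          rt_effect_context = rt_eff$context)
  list(datasets = datasets, behavior = behavior, truth = truth,
       design = design)
}
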