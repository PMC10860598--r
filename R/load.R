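#' Content and context load per trial
#'
#' Derives each trial's memory-load assignment from the stored inter-item
#' distances: content load is 1 when the two samples share a location
#' (`loc_dist == 0`) and 2 otherwise; context load is 1 when they share an
#' orientation (`ori_dist == 0`) and 2 otherwise. The absolute distance
#' levels (location 0/40/80/120/160, orientation 0/30/60/90) are returned for
#' finer binning.
#'
#' @param design A `dsr_design`.
#' @return A tibble with `trial`, `content_load`, `context_load`,
#'   `content_distance`, `context_distance`.
#' @export
load_assignment <- function(design) {
  tibble::tibble(
    trial = design$trial,
    content_load = ifelse(design$loc_dist == 0, 1L, 2L),
    context_load = ifelse(design$ori_dist == 0, 1L, 2L),
    content_distance = abs(design$loc_dist),
    context_distance = abs(design$ori_dist)
  )
}

#' Percent signal change of a trial time course
#'
#' Baseline-corrects a per-TR signal to the first TR of the trial and scales
#' by the run-mean signal intensity:
#' `psc_t = 100 * (x_t - x_1) / max(|run_mean|, eps)`. Because z-scored runs
#' have mean ~0, the denominator is the mean raw intensity of the run, which
#' must be supplied; the convention is recorded so real-data users can
#' substitute a raw-intensity baseline.
#'
#' @param trial_timecourse Per-TR signal for one trial (ROI mean), length
#'   >= 1.
#' @param run_mean Mean signal intensity of the trial's run.
#' @param eps Degeneracy guard for the denominator.
#' @param run_label Optional run identifier for error messages.
#' @return Numeric vector of percent signal change; element 1 is always 0.
#' @export
percent_signal_change <- function(trial_timecourse, run_mean, eps = 1e-6,
                                  run_label = NULL) {
  if (length(trial_timecourse) < 1) stop("empty trial time course")
  if (abs(run_mean) < eps) {
    stop("degenerate percent-signal-change denominator (|run mean| < ", eps,
         ")", if (!is.null(run_label)) paste0(" in run ", run_label))
  }
  100 * (trial_timecourse - trial_timecourse[1]) / abs(run_mean)
}

#' ROI-mean percent-signal-change table
#'
#' Averages a dataset over voxels and converts every trial's 12-TR time
#' course to percent signal change against the first TR, with the run-mean
#' raw intensity as denominator. Apply to the raw (not z-scored) dataset.
#'
#' @param dataset A `bold_dataset`.
#' @return A tibble with `run`, `trial` (global index), `tr`, `psc`.
#' @export
psc_timecourse <- function(dataset) {
  stopifnot(inherits(dataset, "bold_dataset"))
  n_runs <- dim(dataset$data)[1]
  n_tr <- dim(dataset$data)[3]
  tpr <- dim(dataset$data)[4]
  out <- purrr::map(seq_len(n_runs), function(r) {
    block <- dataset$data[r, , , , drop = TRUE] # v x tr x trial
    roi_mean <- apply(block, c(2, 3), mean)     # tr x trial
    run_mean <- mean(block)
    trials <- dataset$design$trial[dataset$design$run == r]
    psc <- apply(roi_mean, 2, percent_signal_change, run_mean = run_mean,
                 run_label = r)
    tibble::tibble(
      run = r,
      trial = rep(trials, each = n_tr),
      tr = rep(seq_len(n_tr), times = tpr),
      psc = as.vector(psc)
    )
  })
  dplyr::bind_rows(out)
}

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style double-gamma HRF: a gamma density peaking ~5 s post-onset minus
#' a 1/6-amplitude undershoot gamma peaking ~15 s, normalized to peak 1.
#'
#' @param t Time in seconds (>= 0; values < 0 return 0).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t) {
  h <- ifelse(t < 0, 0,
              stats::dgamma(t, shape = 6, rate = 1) -
                stats::dgamma(t, shape = 16, rate = 1) / 6)
  h / 0.1754412 # peak value of the canonical shape (at ~5 s), so max ~= 1
}

# Seven task-epoch regressors (onset, duration in seconds within a trial):
# impulses are modeled as 0.1-s events on the convolution grid.
dsr_epochs <- function() {
  tm <- dsr_timing()
  on <- cumsum(c(0, unname(tm)))
  tibble::tibble(
    epoch = c("sample", "delay1_1", "cue1", "delay1_2", "probe1", "delay2",
              "probe2"),
    onset = c(on[1], on[2], on[3], on[4], on[5], on[6], on[9]),
    duration = c(0, tm[["delay1_1"]], 0, tm[["delay1_2"]], 0, 0, 0)
  )
}

# Build the convolved task design matrix for one run, sampled at the
# observed (trial-locked) TRs. Returns a (12 * trials_per_run) x 7 matrix
# whose rows follow acquisition order (TR within trial).
run_task_regressors <- function(onsets, run_duration, n_tr_per_trial = 12L,
                                tr_s = 2, dt = 0.1) {
  ep <- dsr_epochs()
  grid_n <- ceiling(run_duration / dt) + 1L
  grid_t <- (seq_len(grid_n) - 1) * dt
  kern <- hrf_double_gamma(seq(0, 32, by = dt))
  X <- matrix(0, nrow = n_tr_per_trial * length(onsets), ncol = nrow(ep))
  colnames(X) <- ep$epoch
  obs_t <- as.vector(vapply(onsets,
                            function(o) o + (seq_len(n_tr_per_trial) - 1) * tr_s,
                            numeric(n_tr_per_trial)))
  obs_idx <- round(obs_t / dt) + 1L
  for (j in seq_len(nrow(ep))) {
    neural <- numeric(grid_n)
    for (o in onsets) {
      i0 <- round((o + ep$onset[j]) / dt) + 1L
      i1 <- i0 + max(0L, round(ep$duration[j] / dt) - 1L)
      i1 <- min(i1, grid_n)
      if (i0 <= grid_n) neural[i0:i1] <- 1
    }
    conv <- stats::convolve(neural, rev(kern), type = "open")[seq_len(grid_n)] * dt
    X[, j] <- conv[obs_idx]
  }
  X
}

#' GLM-based voxel selection
#'
#' Fits each voxel's trial-locked time series with an ordinary-least-squares
#' GLM containing the seven task-epoch regressors (Sample impulse, Delay 1.1
#' boxcar, Cue 1 impulse, Delay 1.2 boxcar, Probe 1 impulse, Delay 2
#' impulse, Probe 2 impulse), each convolved with the canonical double-gamma
#' HRF sampled at the TR grid, plus per-run intercept and linear/quadratic
#' drift nuisances, and returns the `k` voxels with the strongest coefficient
#' on the target regressor.
#'
#' @param dataset A `bold_dataset` (raw intensities).
#' @param target `"sample"` (early visual selection) or `"delay1_2"`
#'   (IPS-style delay selection).
#' @param k Number of voxels to keep.
#' @return Integer voxel indices, ordered by decreasing target coefficient.
#' @export
glm_voxel_selection <- function(dataset, target = c("sample", "delay1_2"),
                                k = 500L) {
  stopifnot(inherits(dataset, "bold_dataset"))
  target <- match.arg(target)
  v <- dim(dataset$data)[2]
  if (k > v) stop("k (", k, ") exceeds the number of voxels (", v, ")")
  n_runs <- dim(dataset$data)[1]
  n_tr <- dim(dataset$data)[3]
  tpr <- dim(dataset$data)[4]

  blocks <- vector("list", n_runs)
  Xs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    rows <- dataset$design$run == r
    onsets <- dataset$design$onset_s[rows]
    run_dur <- max(onsets) + sum(dsr_timing()) + max(dataset$design$iti[rows])
    Xs[[r]] <- run_task_regressors(onsets, run_dur, n_tr)
    block <- dataset$data[r, , , , drop = TRUE]             # v x tr x trial
    m <- matrix(block, nrow = v)                            # cols: tr fast
    blocks[[r]] <- t(m)                                     # samples x v
  }
  X_task <- do.call(rbind, Xs)
  # per-run intercept + linear + quadratic drift
  n_samp <- n_tr * tpr
  drift <- matrix(0, nrow = n_runs * n_samp, ncol = 3L * n_runs)
  tt <- scale(seq_len(n_samp))
  for (r in seq_len(n_runs)) {
    rws <- (r - 1) * n_samp + seq_len(n_samp)
    drift[rws, (r - 1) * 3 + 1:3] <- cbind(1, tt, tt^2)
  }
  X <- cbind(X_task, drift)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient GLM design matrix")
  Y <- do.call(rbind, blocks)
  beta <- stats::lm.fit(X, Y)$coefficients
  score <- beta[target, ]
  order(score, decreasing = TRUE)[seq_len(k)]
}

#' Load-contrast permutation tests per TR
#'
#' For each subject and TR, averages percent signal change within load-of-1
#' and load-of-2 trials on the requested dimension, then tests the paired
#' load difference across subjects at each TR with a sign-flip permutation
#' test; p values are FDR-corrected across TRs.
#'
#' @param psc_tbl A PSC table with columns `subject`, `trial`, `tr`, `psc`
#'   (e.g. [psc_timecourse()] results row-bound with a `subject` column).
#' @param loads A [load_assignment()] table for the shared design.
#' @param dimension `"content"` or `"context"`.
#' @param n_perm Permutation iterations per TR.
#' @param q FDR level for the rejection mask.
#' @param seed Integer seed.
#' @return A tibble with `tr`, `mean_load1`, `mean_load2`, `diff`, `p`,
#'   `significant` (BH-FDR mask across TRs), `n_perm`.
#' @export
load_timecourse_test <- function(psc_tbl, loads, dimension = c("content", "context"),
                                 n_perm = 10000L, q = 0.05, seed = 1L) {
  dimension <- match.arg(dimension)
  load_col <- paste0(dimension, "_load")
  joined <- dplyr::left_join(psc_tbl, loads[c("trial", load_col)], by = "trial")
  joined$load <- joined[[load_col]]
  chk <- joined |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(has1 = any(.data$load == 1L),
                     has2 = any(.data$load == 2L), .groups = "drop")
  bad <- chk$subject[!(chk$has1 & chk$has2)]
  if (length(bad) > 0) {
    stop("subject(s) ", paste(bad, collapse = ", "),
         " lack trials at one load level; cannot pair")
  }
  per_cell <- joined |>
    dplyr::group_by(.data$subject, .data$tr, .data$load) |>
    dplyr::summarise(psc = mean(.data$psc), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "load", values_from = "psc",
                       names_prefix = "load")
  trs <- sort(unique(per_cell$tr))
  res <- purrr::map(seq_along(trs), function(i) {
    cell <- dplyr::filter(per_cell, .data$tr == trs[i]) |>
      dplyr::arrange(.data$subject)
    tibble::tibble(
      tr = trs[i],
      mean_load1 = mean(cell$load1), mean_load2 = mean(cell$load2),
      diff = mean(cell$load2 - cell$load1),
      p = paired_permutation_test(cell$load2, cell$load1, n_perm = n_perm,
                                  seed = seed + i)
    )
  }) |> dplyr::bind_rows()
  res$significant <- fdr_bh(res$p, q)
  res$n_perm <- as.integer(n_perm)
  res
}

#' Delay-period load sensitivity per subject
#'
#' Mean over the late-delay TRs (default 8-10) of the load-of-2 minus
#' load-of-1 percent-signal-change difference, one value per subject — the
#' neural load-sensitivity score correlated with behavioural load effects.
#'
#' @inheritParams load_timecourse_test
#' @param trs TRs to average (default 8:10, Delay 1.2).
#' @return A tibble with `subject`, `sensitivity`.
#' @export
delay_load_sensitivity <- function(psc_tbl, loads,
                                   dimension = c("content", "context"),
                                   trs = 8:10) {
  dimension <- match.arg(dimension)
  if (!all(trs %in% unique(psc_tbl$tr))) {
    stop("requested TRs ", paste(setdiff(trs, unique(psc_tbl$tr)),
                                 collapse = ", "), " absent from PSC table")
  }
  load_col <- paste0(dimension, "_load")
  joined <- dplyr::left_join(psc_tbl, loads[c("trial", load_col)], by = "trial")
  joined$load <- joined[[load_col]]
  joined |>
    dplyr::filter(.data$tr %in% trs) |>
    dplyr::group_by(.data$subject, .data$load) |>
    dplyr::summarise(psc = mean(.data$psc), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "load", values_from = "psc",
                       names_prefix = "load") |>
    dplyr::transmute(subject = .data$subject,
                     sensitivity = .data$load2 - .data$load1)
}
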