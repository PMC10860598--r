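#' Stimulus and timing constants of the DSR task
#'
#' Base stimulus values and epoch durations for the dual-serial-retrocue
#' (DSR) location-memory task: nine polar-angle locations (20 to 340 degrees
#' in 40-degree steps), six bar orientations (15 to 165 in 30-degree steps),
#' the signed inter-item distance sets, and per-epoch durations in seconds.
#' Probe 2's duration is not independently specified by the task description
#' and is set equal to Probe 1 (2.5 s), which makes each trial 30 s and each
#' 12-trial run 464 s once the mean 8 s ITI and four 2-s dummy TRs are
#' counted.
#'
#' @return `dsr_timing()` returns a named numeric vector of epoch durations
#'   (seconds); the distance/value constants are plain numeric vectors.
#' @export
dsr_timing <- function() {
  c(sample = 2, delay1_1 = 8, cue1 = 2, delay1_2 = 8, probe1 = 2.5,
    delay2_1 = 1, cue2 = 2, delay2_2 = 2, probe2 = 2.5)
}

#' @rdname dsr_timing
#' @export
loc_distances <- function() c(-160, -120, -80, -40, 0, 40, 80, 120, 160)

#' @rdname dsr_timing
#' @export
ori_distances <- function() c(-60, -30, 0, 30, 60, 90)

#' @rdname dsr_timing
#' @export
n_dummy_trs <- function() 4L

#' Enumerate the unique DSR trial types
#'
#' The crossing of signed location distance (9 values), signed orientation
#' distance (6 values) and second-cue status (stay/switch) defines 108 unique
#' trial types.
#'
#' @param loc_dists,ori_dists Signed distance sets, degrees; defaults are the
#'   task's sets.
#' @param cue2_statuses Character vector of second-retrocue statuses.
#' @return A tibble with one row per trial type and columns `loc_dist`,
#'   `ori_dist`, `cue2_status`.
#' @export
#' @examples
#' nrow(enumerate_trial_types())  # 108
enumerate_trial_types <- function(loc_dists = loc_distances(),
                                  ori_dists = ori_distances(),
                                  cue2_statuses = c("stay", "switch")) {
  tidyr::expand_grid(loc_dist = loc_dists, ori_dist = ori_dists,
                     cue2_status = cue2_statuses)
}

# Deal `n` items from a balanced pool of `values`, shuffled; n must be a
# multiple of length(values) for exact balance, otherwise the remainder is
# drawn without replacement from a reshuffled pool.
balanced_sample <- function(values, n) {
  full <- rep(values, length.out = n - n %% length(values))
  extra <- if (n %% length(values)) sample(values, n %% length(values)) else NULL
  sample(c(full, extra))
}

#' Build a counterbalanced DSR trial schedule
#'
#' Generates a full per-subject schedule: `reps` copies of each of the 108
#' trial types, randomly ordered and dealt into runs of 12 trials. Sample 1's
#' location is drawn uniformly from the nine base polar angles and its
#' orientation from the six base orientations; sample 2 is placed at the
#' cell's signed distances. A shared location jitter (uniform over
#' `jitter_range`) is added to both sample locations. The first retrocue
#' (`cued_item`) is near-balanced within each trial-type cell and exactly
#' balanced globally; probe match/nonmatch is balanced 50/50 with nonmatch
#' offsets balanced over 15/25/35 degrees; ITIs are balanced within each run
#' (four each of 6, 8 and 10 s) so every run lasts exactly 464 s including
#' the four dummy TRs.
#'
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @param reps Copies of each trial type (default 3, giving 324 trials).
#' @param jitter_range Length-2 numeric range (degrees) for the shared
#'   location jitter; default `c(0, 10)`.
#' @return A tibble of class `dsr_design`, one row per trial, with columns
#'   `run`, `trial`, `loc1`, `ori1`, `loc2`, `ori2`, `jitter`, `loc_dist`,
#'   `ori_dist`, `cued_item`, `cue2_status`, `probe_match`, `probe_offset`
#'   (NA on match trials), `iti`, `onset_s`. Timing metadata are attached as
#'   attributes `timing` and `n_dummy_trs`.
#' @export
#' @examples
#' d <- build_design(seed = 1)
#' nrow(d)              # 324
#' design_summary(d)
build_design <- function(seed, reps = 3L, jitter_range = c(0, 10)) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stopifnot(reps >= 1L)
  types <- enumerate_trial_types()
  n_trials <- nrow(types) * reps
  if (n_trials %% 12L != 0L) {
    stop("schedule error: ", reps, " reps x ", nrow(types),
         " trial types = ", n_trials, " trials leaves a remainder of ",
         n_trials %% 12L, " when dealt into runs of 12")
  }
  n_runs <- n_trials %/% 12L

  set.seed(as.integer(seed))

  trials <- types[rep(seq_len(nrow(types)), each = reps), ]
  # near-balanced first cue within each cell, exactly balanced overall: each
  # cell alternates items 1/2 and, when reps is odd, half the cells (chosen
  # at random) give the odd rep to item 1, half to item 2
  cue_extra <- sample(rep(1:2, length.out = nrow(types)))
  trials$cued_item <- as.vector(vapply(
    seq_len(nrow(types)),
    function(i) {
      cell <- rep(1:2, length.out = reps)
      if (reps %% 2L == 1L) cell[reps] <- cue_extra[i]
      as.integer(cell[sample.int(length(cell))])
    },
    integer(reps)
  ))
  trials <- trials[sample(nrow(trials)), ]

  base_locs <- seq(20, 340, by = 40)
  base_oris <- seq(15, 165, by = 30)
  jitter <- stats::runif(n_trials, jitter_range[1], jitter_range[2])
  loc1 <- wrap_angle(sample(base_locs, n_trials, replace = TRUE) + jitter, 360)
  ori1 <- sample(base_oris, n_trials, replace = TRUE)
  loc2 <- wrap_angle(loc1 + trials$loc_dist, 360)
  ori2 <- wrap_angle(ori1 + trials$ori_dist, 180)

  probe_match <- balanced_sample(c(TRUE, FALSE), n_trials)
  probe_offset <- rep(NA_real_, n_trials)
  probe_offset[!probe_match] <- balanced_sample(c(15, 25, 35), sum(!probe_match))

  # ITIs balanced within each run so all runs have identical duration
  iti <- as.vector(vapply(seq_len(n_runs),
                          function(r) balanced_sample(c(6, 8, 10), 12L),
                          numeric(12L)))

  trial_len <- sum(dsr_timing())
  run <- rep(seq_len(n_runs), each = 12L)
  onset_s <- numeric(n_trials)
  for (r in seq_len(n_runs)) {
    idx <- which(run == r)
    starts <- 2 * n_dummy_trs() +
      cumsum(c(0, (trial_len + iti[idx])[-12L]))
    onset_s[idx] <- starts
  }

  design <- tibble::tibble(
    run = run, trial = seq_len(n_trials),
    loc1 = loc1, ori1 = ori1, loc2 = loc2, ori2 = ori2,
    jitter = jitter,
    loc_dist = trials$loc_dist, ori_dist = trials$ori_dist,
    cued_item = trials$cued_item, cue2_status = trials$cue2_status,
    probe_match = probe_match, probe_offset = probe_offset,
    iti = iti, onset_s = onset_s
  )
  attr(design, "timing") <- dsr_timing()
  attr(design, "n_dummy_trs") <- n_dummy_trs()
  class(design) <- c("dsr_design", class(design))
  design
}

#' Summarize a DSR design
#'
#' Reports the counterbalancing proportions and counts a valid schedule must
#' satisfy: the proportion of trials with zero orientation distance (1/6),
#' zero location distance (1/9), and a switch second cue (1/2); per-cell
#' counts over the 108 trial types; trials per run; and the run duration in
#' seconds including dummy TRs.
#'
#' @param design A `dsr_design` tibble from [build_design()].
#' @return A list with elements `proportions` (tibble), `cell_counts`
#'   (tibble with `n` per trial type), `trials_per_run` (tibble) and
#'   `run_duration_s` (numeric, per run).
#' @export
design_summary <- function(design) {
  stopifnot(inherits(design, "dsr_design"))
  if (nrow(design) == 0L) stop("design is empty")
  props <- tibble::tibble(
    measure = c("ori_dist_zero", "loc_dist_zero", "cue2_switch"),
    proportion = c(mean(design$ori_dist == 0),
                   mean(design$loc_dist == 0),
                   mean(design$cue2_status == "switch"))
  )
  cells <- dplyr::count(tibble::as_tibble(design),
                        .data$loc_dist, .data$ori_dist, .data$cue2_status)
  per_run <- dplyr::count(tibble::as_tibble(design), .data$run)
  trial_len <- sum(attr(design, "timing"))
  run_dur <- vapply(
    split(design$iti, design$run),
    function(itis) 2 * attr(design, "n_dummy_trs") +
      sum(trial_len + itis),
    numeric(1)
  )
  list(proportions = props, cell_counts = cells, trials_per_run = per_run,
       run_duration_s = unname(run_dur))
}

#' Signed circular distance between stored sample features
#'
#' Recomputes the signed sample2 - sample1 distances from the stored feature
#' values, wrapped to the printed distance sets; used to validate a stored
#' design.
#'
#' @param design A `dsr_design`.
#' @return A tibble with `trial`, `loc_dist_recovered`, `ori_dist_recovered`.
#' @keywords internal
#' @export
recover_distances <- function(design) {
  tibble::tibble(
    trial = design$trial,
    loc_dist_recovered = wrap_signed(design$loc2 - design$loc1, 360),
    ori_dist_recovered = wrap_signed(design$ori2 - design$ori1, 180)
  )
}

#' Read and write DSR event tables
#'
#' A design round-trips as a tab-separated events table, one row per trial,
#' with angles printed to three decimals. `read_design()` restores the
#' `dsr_design` class and timing attributes.
#'
#' @param design A `dsr_design`.
#' @param path File path for the TSV.
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   a `dsr_design` tibble.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "dsr_design"))
  out <- tibble::as_tibble(design)
  ang <- c("loc1", "ori1", "loc2", "ori2", "jitter")
  out[ang] <- lapply(out[ang], function(x) sprintf("%.3f", x))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         cue2_status = readr::col_character(),
                         probe_match = readr::col_logical()
                       ))
  d$cued_item <- as.integer(d$cued_item)
  attr(d, "timing") <- dsr_timing()
  attr(d, "n_dummy_trs") <- n_dummy_trs()
  class(d) <- c("dsr_design", class(d))
  d
}

#' Per-item feature labels implied by the first retrocue
#'
#' After Cue 1 the cued sample is the prioritized memory item (PMI) and the
#' other the unprioritized item (UMI). Returns each trial's PMI/UMI location
#' and orientation, the labels used to train (PMI) and recenter (PMI or UMI)
#' encoding models.
#'
#' @param design A `dsr_design`.
#' @return A tibble with `trial`, `run`, `pmi_loc`, `pmi_ori`, `umi_loc`,
#'   `umi_ori`.
#' @export
item_features <- function(design) {
  cued1 <- design$cued_item == 1L
  tibble::tibble(
    trial = design$trial, run = design$run,
    pmi_loc = ifelse(cued1, design$loc1, design$loc2),
    pmi_ori = ifelse(cued1, design$ori1, design$ori2),
    umi_loc = ifelse(cued1, design$loc2, design$loc1),
    umi_ori = ifelse(cued1, design$ori2, design$ori1)
  )
}
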