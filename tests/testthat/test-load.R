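test_that("load binning is a pure function of the design distances", {
  d <- build_design(seed = 6)
  la <- load_assignment(d)
  expect_equal(sum(la$content_load == 1L), 36L) # 1/9 of 324
  expect_equal(sum(la$context_load == 1L), 54L) # 1/6 of 324
  expect_setequal(unique(la$content_distance), c(0, 40, 80, 120, 160))
  expect_setequal(unique(la$context_distance), c(0, 30, 60, 90))
  expect_identical(la$content_load, ifelse(d$loc_dist == 0, 1L, 2L))
})

test_that("percent signal change follows the stated baseline convention", {
  expect_equal(percent_signal_change(rep(7, 12), run_mean = 7), rep(0, 12))
  x <- c(100, 101, 100.5, 99, 102, rep(100, 7))
  psc <- percent_signal_change(x, run_mean = 100)
  expect_equal(psc[1], 0)
  expect_equal(psc[5], 2)
  expect_error(percent_signal_change(x, run_mean = 1e-9, run_label = 3),
               "run 3")
})

test_that("dataset-level PSC is zero at TR 1 and scales with the baseline", {
  d <- small_design()
  ds <- simulate_subject(d, synth_config(n_voxels = 10L, noise_sd = 0.3,
                                         seed = 14L))
  psc <- psc_timecourse(ds)
  expect_equal(nrow(psc), 108L * 12L)
  expect_true(all(psc$psc[psc$tr == 1] == 0))
  expect_true(all(is.finite(psc$psc)))
})

test_that("the canonical HRF peaks around 5 s with a late undershoot", {
  t <- seq(0, 30, by = 0.1)
  h <- hrf_double_gamma(t)
  expect_equal(max(h), 1, tolerance = 1e-3)
  expect_equal(t[which.max(h)], 5, tolerance = 0.3)
  expect_lt(min(h[t > 10]), 0)       # undershoot
  expect_equal(hrf_double_gamma(-2), 0)
})

test_that("GLM voxel selection ranks a constructed sample-epoch voxel first", {
  d <- small_design()
  cfg <- synth_config(n_voxels = 10L, noise_sd = 0.05, seed = 15L,
                      amp_profile = list(location = list(pmi = rep(0, 12),
                                                         umi = rep(0, 12)),
                                         orientation = list(pmi = rep(0, 12),
                                                            umi = rep(0, 12))),
                      load_effect = list(content = rep(0, 12),
                                         context = rep(0, 12)))
  ds <- simulate_subject(d, cfg) # baseline + noise only
  # inject a sample-evoked HRF response into voxel 7 on every trial
  resp <- hrf_double_gamma(seq(0, by = 2, length.out = 12))
  for (r in seq_len(dim(ds$data)[1])) {
    for (j in seq_len(dim(ds$data)[4])) {
      ds$data[r, 7, , j] <- ds$data[r, 7, , j] + 5 * resp
    }
  }
  sel <- glm_voxel_selection(ds, target = "sample", k = 3L)
  expect_length(sel, 3L)
  expect_equal(sel[1], 7L)
  expect_error(glm_voxel_selection(ds, "sample", k = 50L), "exceeds")
})

test_that("the task GLM contains exactly the seven epoch regressors", {
  ep <- dsriem:::dsr_epochs()
  expect_equal(nrow(ep), 7L)
  expect_equal(ep$epoch, c("sample", "delay1_1", "cue1", "delay1_2",
                           "probe1", "delay2", "probe2"))
  expect_equal(ep$onset, c(0, 2, 10, 12, 20, 22.5, 27.5))
  X <- dsriem:::run_task_regressors(onsets = c(8, 46), run_duration = 100)
  expect_equal(ncol(X), 7L)
  expect_equal(nrow(X), 24L)
})

test_that("load contrasts are detected exactly at the injected TRs", {
  d <- small_design()
  loads <- load_assignment(d)
  inject <- list(content = c(0, 0, 0, 0, 0, 0, 2, 2, 2, 2, 0, 0),
                 context = rep(0, 12))
  # stimulus amplitudes held at zero: with tuned signal present, the
  # ROI-mean response covaries with inter-item distance in small voxel
  # samples, which would contaminate the pure load contrast
  amp0 <- list(location = list(pmi = rep(0, 12), umi = rep(0, 12)),
               orientation = list(pmi = rep(0, 12), umi = rep(0, 12)))
  # 12 subjects: the smallest attainable sign-flip p must clear the BH
  # threshold at the injected TRs (with 6 subjects min p is 2/2^6 ~ 0.03)
  psc <- purrr::map(1:12, function(s) {
    cfg <- synth_config(n_voxels = 10L, noise_sd = 0, weight_noise_sd = 0,
                        amp_profile = amp0,
                        load_effect = inject, seed = 30L + s)
    tibble::add_column(psc_timecourse(simulate_subject(d, cfg)),
                       subject = s, .before = 1)
  }) |> dplyr::bind_rows()
  res <- load_timecourse_test(psc, loads, "content", n_perm = 300, seed = 2)
  expect_equal(res$tr[res$significant], 7:10)
  expect_true(all(res$p[res$tr %in% 7:10] <= 0.01))
  expect_true(all(res$p[!res$tr %in% 7:10] == 1))
  # the context contrast stays negligible: content load is exactly balanced
  # across context-load groups, leaving only per-run PSC-denominator rounding
  res_ctx <- load_timecourse_test(psc, loads, "context", n_perm = 300,
                                  seed = 3)
  expect_lt(max(abs(res_ctx$diff)), 1e-2)
  expect_gt(min(res$diff[res$tr %in% 7:10]) / max(abs(res_ctx$diff)), 50)
})

test_that("delay-period load sensitivity recovers the injected gain", {
  d <- small_design()
  loads <- load_assignment(d)
  base_effect <- list(content = c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0),
                      context = rep(0, 12))
  gains <- c(0.5, 1, 2)
  amp0 <- list(location = list(pmi = rep(0, 12), umi = rep(0, 12)),
               orientation = list(pmi = rep(0, 12), umi = rep(0, 12)))
  psc <- purrr::map(seq_along(gains), function(s) {
    cfg <- synth_config(n_voxels = 10L, noise_sd = 0, weight_noise_sd = 0,
                        amp_profile = amp0,
                        load_effect = purrr::map(base_effect, ~ .x * gains[s]),
                        seed = 40L + s)
    tibble::add_column(psc_timecourse(simulate_subject(d, cfg)),
                       subject = s, .before = 1)
  }) |> dplyr::bind_rows()
  sens <- delay_load_sensitivity(psc, loads, "content")
  # equal group means at uninjected TRs cancel; PSC scales the raw gain by
  # 100 / run-mean intensity, and the run mean is dominated by the baseline
  expect_equal(nrow(sens), 3L)
  expect_gt(cor(sens$sensitivity, gains), 0.999)
  ratio <- sens$sensitivity / gains
  expect_equal(ratio / ratio[1], rep(1, 3), tolerance = 0.05)
  expect_error(delay_load_sensitivity(psc, loads, "content", trs = 13:14),
               "absent")
  # zero injected effect gives zero sensitivity
  cfg0 <- synth_config(n_voxels = 10L, noise_sd = 0, weight_noise_sd = 0,
                       amp_profile = amp0,
                       load_effect = list(content = rep(0, 12),
                                          context = rep(0, 12)), seed = 50L)
  psc0 <- tibble::add_column(psc_timecourse(simulate_subject(d, cfg0)),
                             subject = 1L, .before = 1)
  sens0 <- delay_load_sensitivity(psc0, loads, "content")
  expect_equal(sens0$sensitivity, 0, tolerance = 1e-10)
})
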