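#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: the design seed and
#' repetitions, per-ROI synthetic configurations (the ROI labels are
#' synthetic regions with independent generative regimes, so each model's
#' predicted pattern can be instantiated), the TR of interest, resampling
#' iteration counts, and significance/FDR levels.
#'
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param reps Trial-type repetitions for the design (default 3 = 324 trials).
#' @param n_subjects Cohort size (default 24).
#' @param rois Named list of [synth_config()] objects, one per region label.
#' @param trs TRs to reconstruct for the time-course tables.
#' @param tr_of_interest TR for the preregistered cell tests (default 10,
#'   18-20 s after trial onset, the final TR of Delay 1.2).
#' @param n_boot Bootstrap iterations for slope tests.
#' @param n_perm Permutation iterations for load tests.
#' @param alpha Significance level for cell classification.
#' @param q FDR level.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, reps = 3L, n_subjects = 24L,
                            rois = list(evc = synth_config(),
                                        ips = synth_config()),
                            trs = 1:12, tr_of_interest = 10L,
                            n_boot = 10000L, n_perm = 10000L,
                            alpha = 0.05, q = 0.05) {
  stopifnot(tr_of_interest %in% 1:12, alpha > 0, alpha < 1, q > 0, q < 1)
  stopifnot(length(rois) >= 1, !is.null(names(rois)))
  for (r in rois) stopifnot(inherits(r, "synth_config"))
  stopifnot(n_subjects >= 2)
  structure(
    list(seed = as.integer(seed), reps = as.integer(reps),
         n_subjects = as.integer(n_subjects), rois = rois,
         trs = as.integer(trs), tr_of_interest = as.integer(tr_of_interest),
         n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
         alpha = alpha, q = q),
    class = "pipeline_config"
  )
}

# subject-level mean recentered curves for one ROI cohort:
# returns array n_subjects x k x n_trs
cohort_curves <- function(datasets, feature_dim, test_item, trs) {
  k <- if (feature_dim == "location") 9L else 6L
  out <- array(NA_real_, dim = c(length(datasets), k, length(trs)))
  for (s in seq_along(datasets)) {
    rec <- crossval_reconstruct_timecourse(datasets[[s]], feature_dim,
                                           test_item, trs)
    out[s, , ] <- t(rec$mean_curves)
  }
  out
}

#' Run the full simulate-reconstruct-test-adjudicate analysis
#'
#' For each configured ROI: simulates a cohort with coupled behaviour,
#' z-scores runs, computes leave-one-run-out reconstructions of location
#' (content) and orientation (context) for PMI and UMI over the requested
#' TRs, tests the slope at every TR (bootstrap over subjects, FDR across TRs
#' within each trace) and the PMI-UMI difference, evaluates the eight
#' preregistered cells at the TR of interest (FDR-corrected across cells),
#' runs the univariate load permutation tests and the brain-behaviour
#' correlations, and adjudicates the three models against the observed cell
#' pattern. Deterministic given the config.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `analysis_report`: a list of tibbles `cells`,
#'   `difference_tests`, `timecourse`, `load_tests`, `brain_behavior`,
#'   `behavior`, the `adjudication` object, and `provenance`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 4L + length(cfg$rois))
  design <- build_design(seed = stage_seeds[1], reps = cfg$reps)
  loads <- load_assignment(design)
  dims <- c(location = "content", orientation = "context")
  ti <- match(cfg$tr_of_interest, cfg$trs)
  if (is.na(ti)) stop("tr_of_interest must be among the reconstructed trs")

  cells <- list(); diffs <- list(); tc <- list()
  load_tests <- list(); bb <- list(); behav <- list()
  for (ri in seq_along(cfg$rois)) {
    roi <- names(cfg$rois)[ri]
    scfg <- cfg$rois[[ri]]
    scfg$seed <- stage_seeds[4L + ri]
    cohort <- simulate_cohort_with_behavior(cfg$n_subjects, scfg, design)
    zdata <- lapply(cohort$datasets, zscore_runs)

    # percent signal change on raw intensities, before discarding the data
    psc <- purrr::imap(cohort$datasets,
                       ~ tibble::add_column(psc_timecourse(.x),
                                            subject = .y, .before = 1)) |>
      dplyr::bind_rows()
    cohort$datasets <- NULL

    for (fd in names(dims)) {
      curves <- list(
        pmi = cohort_curves(zdata, fd, "pmi", cfg$trs),
        umi = cohort_curves(zdata, fd, "umi", cfg$trs)
      )
      offsets <- if (fd == "location") location_basis()$offsets else
        orientation_basis()$offsets
      for (item in c("pmi", "umi")) {
        tests <- purrr::map(seq_along(cfg$trs), function(i) {
          st <- bootstrap_slope_test(curves[[item]][, , i], offsets,
                                     n_boot = cfg$n_boot,
                                     seed = stage_seeds[2] + 1000L * ri + 100L *
                                       match(fd, names(dims)) + 10L *
                                       match(item, c("pmi", "umi")) + i)
          dplyr::bind_cols(tibble::tibble(tr = cfg$trs[i]), tidy(st))
        }) |> dplyr::bind_rows()
        tests$p_fdr_trs <- stats::p.adjust(tests$p_value, "BH")
        tc[[paste(roi, fd, item)]] <- tibble::add_column(
          tests, roi = roi, dimension = dims[[fd]], item = item, .before = 1)
        cells[[paste(roi, fd, item)]] <- tibble::tibble(
          roi = roi, dimension = dims[[fd]], item = item,
          tr = cfg$tr_of_interest,
          slope = tests$estimate[ti], p_raw = tests$p_value[ti],
          p_bound_flag = tests$p_bound_flag[ti],
          n_boot = cfg$n_boot, seed = tests$seed[ti]
        )
      }
      dt <- bootstrap_difference_test(curves$pmi[, , ti], curves$umi[, , ti],
                                      offsets, n_boot = cfg$n_boot,
                                      seed = stage_seeds[3] + 10L * ri +
                                        match(fd, names(dims)))
      diffs[[paste(roi, fd)]] <- tibble::add_column(
        tidy(dt), roi = roi, dimension = dims[[fd]],
        tr = cfg$tr_of_interest, .before = 1)
    }

    for (dm in c("content", "context")) {
      lt <- load_timecourse_test(psc, loads, dm, n_perm = cfg$n_perm,
                                 q = cfg$q, seed = stage_seeds[4] + 10L * ri +
                                   match(dm, c("content", "context")))
      load_tests[[paste(roi, dm)]] <- tibble::add_column(
        lt, roi = roi, dimension = dm, .before = 1)
      sens <- delay_load_sensitivity(psc, loads, dm)
      rt_eff <- cohort$behavior |>
        dplyr::filter(.data$dimension == dm) |>
        tidyr::pivot_wider(names_from = "load", values_from = "rt",
                           names_prefix = "load") |>
        dplyr::arrange(.data$subject)
      pc <- pearson_correlation(sens$sensitivity,
                                rt_eff$load2 - rt_eff$load1)
      bb[[paste(roi, dm)]] <- tibble::add_column(pc, roi = roi,
                                                 dimension = dm, .before = 1)
    }
    behav[[roi]] <- tibble::add_column(cohort$behavior, roi = roi, .before = 1)
  }

  cells <- dplyr::bind_rows(cells)
  cells$p <- stats::p.adjust(cells$p_raw, "BH") # FDR across the 8 cells
  adj <- adjudicate_models(cells[c("roi", "dimension", "item", "slope", "p")],
                           alpha = cfg$alpha)
  structure(
    list(cells = cells, difference_tests = dplyr::bind_rows(diffs),
         timecourse = dplyr::bind_rows(tc),
         load_tests = dplyr::bind_rows(load_tests),
         brain_behavior = dplyr::bind_rows(bb),
         behavior = dplyr::bind_rows(behav),
         adjudication = adj,
         provenance = list(config_hash = rlang::hash(unclass(cfg)),
                           seed = cfg$seed, stage_seeds = stage_seeds,
                           n_boot = cfg$n_boot, n_perm = cfg$n_perm,
                           package_version = as.character(utils::packageVersion("dsriem")))),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> ", nrow(x$cells), " preregistered cells, ",
      nrow(x$timecourse), " time-course tests\n", sep = "")
  print(x$adjudication)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes the report tables as TSV (`cells.tsv`, `difference_tests.tsv`,
#' `timecourse.tsv`, `load_tests.tsv`, `brain_behavior.tsv`,
#' `behavior.tsv`), the adjudication and provenance as JSON, and a short
#' plain-text log.
#'
#' @param report An `analysis_report`.
#' @param outdir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  tabs <- c("cells", "difference_tests", "timecourse", "load_tests",
            "brain_behavior", "behavior")
  paths <- character(0)
  for (t in tabs) {
    p <- file.path(outdir, paste0(t, ".tsv"))
    readr::write_tsv(report[[t]], p)
    paths <- c(paths, p)
  }
  adj_path <- file.path(outdir, "adjudication.json")
  jsonlite::write_json(
    list(match_counts = as.list(report$adjudication$match_counts),
         alpha = report$adjudication$alpha,
         table = report$adjudication$table),
    adj_path, auto_unbox = TRUE, digits = NA)
  prov_path <- file.path(outdir, "provenance.json")
  jsonlite::write_json(report$provenance, prov_path, auto_unbox = TRUE,
                       digits = NA)
  log_path <- file.path(outdir, "report.log")
  writeLines(c(
    paste0("dsriem analysis report (config hash ",
           report$provenance$config_hash, ")"),
    paste0("cells: ", nrow(report$cells)),
    paste0("time-course tests: ", nrow(report$timecourse)),
    paste0("load tests: ", nrow(report$load_tests)),
    paste0("model matches: ",
           paste(names(report$adjudication$match_counts),
                 report$adjudication$match_counts, sep = "=",
                 collapse = ", "))
  ), log_path)
  invisible(c(paths, adj_path, prov_path, log_path))
}
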