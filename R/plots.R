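#' Plot a reconstruction time course
#'
#' Recentered channel-response curves, one panel per TR (or a single panel
#' when one TR was reconstructed), response against channel offset in
#' degrees.
#'
#' @param object An `iem_recon`.
#' @param trs Optional subset of TRs to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iem_recon
#' @export
autoplot.iem_recon <- function(object, trs = NULL, ...) {
  df <- tidy(object)
  if (!is.null(trs)) df <- dplyr::filter(df, .data$tr %in% trs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel_offset_deg,
                                   y = .data$response)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~tr, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "channel offset (deg)", y = "channel response",
      title = paste0(object$feature_dim, " reconstruction, ",
                     toupper(object$item))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap slope distribution
#'
#' Histogram of the bootstrap distribution of the (difference in) mean
#' reconstruction slope, with the point estimate marked.
#'
#' @param object A `slope_test`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot slope_test
#' @export
autoplot.slope_test <- function(object, bins = 60, ...) {
  df <- tibble::tibble(slope = object$boot_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slope)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$point_estimate,
                        colour = "firebrick") +
    ggplot2::labs(
      x = paste0("bootstrap mean ", gsub("_", " ", object$statistic)),
      y = "count",
      title = sprintf("%s: estimate %.3g, p %s %.3g (%d iterations)",
                      object$statistic, object$point_estimate,
                      if (object$p_bound_flag) "<" else "=",
                      object$p_two_tailed, object$n_boot)
    ) +
    ggplot2::theme_minimal()
}

#' Plot load-contrast time courses
#'
#' Mean percent signal change by load level per TR, with significant TRs
#' (FDR-corrected load contrast) marked.
#'
#' @param load_test Output of [load_timecourse_test()].
#' @return A ggplot object.
#' @export
plot_load_timecourse <- function(load_test) {
  df <- tidyr::pivot_longer(load_test, c("mean_load1", "mean_load2"),
                            names_to = "load", values_to = "psc")
  df$load <- ifelse(df$load == "mean_load1", "load 1", "load 2")
  sig <- dplyr::filter(load_test, .data$significant)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tr, y = .data$psc,
                                   colour = .data$load)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = sig,
                        ggplot2::aes(x = .data$tr,
                                     y = pmax(.data$mean_load1,
                                              .data$mean_load2) * 1.08),
                        inherit.aes = FALSE, shape = 8) +
    ggplot2::labs(x = "TR (2 s)", y = "percent signal change",
                  colour = NULL,
                  title = "load-of-1 vs load-of-2 time course") +
    ggplot2::theme_minimal()
}
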