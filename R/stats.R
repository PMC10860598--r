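#' Collapse-and-slope statistic for a recentered reconstruction
#'
#' Quantifies a recentered channel-response curve by pairing channels with
#' equal absolute offset from the 0-degree center, averaging each pair (an
#' unpaired half-period channel, e.g. the +90-degree orientation channel,
#' enters as its own point), ordering the collapsed values from the farthest
#' offset to the center, and regressing them on their rank (0, 1, 2, ...).
#' A center-peaked curve therefore yields a positive slope, a center-inverted
#' (remapped) curve a negative slope, and the magnitude indexes the precision
#' of the reconstruction.
#'
#' @param curve Numeric recentered channel vector (length k).
#' @param offsets Signed channel offsets in degrees, as produced by
#'   recentering (must contain 0; e.g. `location_basis()$offsets`).
#' @return The least-squares slope (response units per distance rank).
#' @export
#' @examples
#' b <- location_basis()
#' reconstruction_slope(channel_response(b, 180), b$offsets)
reconstruction_slope <- function(curve, offsets) {
  if (length(curve) != length(offsets)) {
    stop("curve and offsets must have equal length")
  }
  if (!any(offsets == 0)) {
    stop("offsets contain no 0-degree center; recenter the reconstruction first")
  }
  collapsed <- collapse_curve(curve, offsets)
  x <- collapsed$rank
  y <- collapsed$response
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' @rdname reconstruction_slope
#' @return `collapse_curve()` returns a tibble with `abs_offset_deg`, `rank`
#'   (0 = farthest from center) and the pair-averaged `response`.
#' @export
collapse_curve <- function(curve, offsets) {
  a <- round(abs(offsets), 6)
  agg <- tapply(curve, a, mean)
  abs_off <- as.numeric(names(agg))
  ord <- order(abs_off, decreasing = TRUE)
  tibble::tibble(abs_offset_deg = abs_off[ord],
                 rank = seq_along(ord) - 1L,
                 response = as.numeric(agg[ord]))
}

# slopes of each row of a subjects x channels curve matrix
curve_matrix_slopes <- function(curves, offsets) {
  apply(as.matrix(curves), 1, reconstruction_slope, offsets = offsets)
}

new_slope_test <- function(per_subject_slopes, point_estimate, boot, n_boot,
                           seed, statistic) {
  pos <- mean(boot > 0)
  neg <- mean(boot < 0)
  degenerate <- all(boot == 0)
  if (degenerate) {
    p <- 1
    p_bound <- FALSE
  } else {
    p <- 2 * min(pos, neg)
    p_bound <- p == 0
    if (p_bound) p <- 2 / n_boot # one side empty: true p unresolvable at this B
    p <- min(p, 1)
  }
  structure(
    list(per_subject_slopes = per_subject_slopes,
         point_estimate = point_estimate, boot_distribution = boot,
         p_two_tailed = p, p_bound_flag = p_bound, degenerate = degenerate,
         n_boot = n_boot, seed = seed, statistic = statistic),
    class = "slope_test"
  )
}

#' Bootstrap test of a reconstruction slope
#'
#' Resamples subjects with replacement, averages the resampled subjects'
#' recentered curves, and computes the collapse-and-slope statistic of the
#' average, repeated `n_boot` times. The two-tailed p value is twice the
#' smaller of the proportions of positive and of negative bootstrap slopes;
#' when one sign is absent the p value is reported as the bound `2 / n_boot`
#' (flagged), and an all-zero bootstrap distribution reports p = 1.
#'
#' Because the slope is linear in the curve, the slope of an averaged curve
#' equals the average of the subject slopes; resampling is carried out on the
#' per-subject slopes, which is numerically identical and much faster.
#'
#' @param curves `n_subjects x k` matrix of per-subject recentered curves.
#' @param offsets Signed channel offsets (degrees) of the curve columns.
#' @param n_boot Bootstrap iterations (default 10000).
#' @param seed Integer seed for the resampling.
#' @return An object of class `slope_test`; see [tidy.slope_test()].
#' @export
bootstrap_slope_test <- function(curves, offsets, n_boot = 10000L, seed = 1L) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < 2) stop("bootstrap requires >= 2 subjects")
  slopes <- curve_matrix_slopes(curves, offsets)
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boot <- colMeans(matrix(slopes[idx], nrow = n))
  new_slope_test(slopes, mean(slopes), boot, n_boot, seed, "slope")
}

#' Bootstrap test of a paired slope difference
#'
#' Resamples subjects with replacement (the same draw indexing both
#' conditions) and computes the difference between the mean slope of
#' condition A and condition B per iteration; the p-value rule is the same
#' as in [bootstrap_slope_test()].
#'
#' @param curves_a,curves_b `n_subjects x k` matrices of paired per-subject
#'   curves (same subject order).
#' @inheritParams bootstrap_slope_test
#' @return A `slope_test` whose statistic is the slope difference A - B.
#' @export
bootstrap_difference_test <- function(curves_a, curves_b, offsets,
                                      n_boot = 10000L, seed = 1L) {
  curves_a <- as.matrix(curves_a)
  curves_b <- as.matrix(curves_b)
  if (nrow(curves_a) != nrow(curves_b)) {
    stop("curves_a and curves_b must contain the same (paired) subjects")
  }
  n <- nrow(curves_a)
  if (n < 2) stop("bootstrap requires >= 2 subjects")
  d <- curve_matrix_slopes(curves_a, offsets) -
    curve_matrix_slopes(curves_b, offsets)
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boot <- colMeans(matrix(d[idx], nrow = n))
  new_slope_test(d, mean(d), boot, n_boot, seed, "slope_difference")
}

#' @export
print.slope_test <- function(x, ...) {
  cat("<slope_test> ", x$statistic, ": estimate ",
      signif(x$point_estimate, 4), ", p ",
      if (x$p_bound_flag) "< " else "= ", signif(x$p_two_tailed, 4),
      " (", x$n_boot, " bootstrap iterations, n = ",
      length(x$per_subject_slopes), ")\n", sep = "")
  invisible(x)
}

#' Tidy and glance methods for slope tests
#'
#' @param x A `slope_test`.
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble with `statistic`, `estimate`,
#'   `p_value`, `p_bound_flag`, `n_subjects`, `n_boot`, `seed`; `glance()`
#'   adds the bootstrap distribution's summary quantiles.
#' @method tidy slope_test
#' @export
tidy.slope_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, estimate = x$point_estimate,
                 p_value = x$p_two_tailed, p_bound_flag = x$p_bound_flag,
                 n_subjects = length(x$per_subject_slopes),
                 n_boot = x$n_boot, seed = x$seed)
}

#' @rdname tidy.slope_test
#' @method glance slope_test
#' @export
glance.slope_test <- function(x, ...) {
  q <- stats::quantile(x$boot_distribution, c(0.025, 0.5, 0.975))
  dplyr::bind_cols(tidy.slope_test(x),
                   tibble::tibble(boot_q025 = q[[1]], boot_median = q[[2]],
                                  boot_q975 = q[[3]],
                                  degenerate = x$degenerate))
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up false-discovery-rate control at level `q`.
#'
#' @param p_values Numeric p values in [0, 1].
#' @param q FDR level in (0, 1).
#' @return Logical vector: TRUE where the hypothesis is rejected.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("q must be in (0, 1)")
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must be in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Required sample size for a one-sample t test
#'
#' Smallest n such that a one-sample t test with noncentrality
#' \eqn{d \sqrt{n}} and n - 1 degrees of freedom attains the target power at
#' the given alpha, using the exact noncentral-t power function (no normal
#' approximation).
#'
#' @param d Cohen's d (> 0).
#' @param power Target power in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @param tail `"one"` or `"two"`.
#' @return The smallest integer n meeting the target.
#' @export
#' @examples
#' required_sample_size(0.62, 0.90, 0.05, "one")  # 24
required_sample_size <- function(d, power = 0.90, alpha = 0.05,
                                 tail = c("one", "two")) {
  tail <- match.arg(tail)
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  pw <- function(n) {
    df <- n - 1
    ncp <- d * sqrt(n)
    if (tail == "one") {
      1 - stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp)
    } else {
      crit <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(crit, df, ncp = ncp) + stats::pt(-crit, df, ncp = ncp)
    }
  }
  for (n in 2:1e6) {
    if (pw(n) >= power) return(n)
  }
  stop("target power unreachable within n <= 1e6")
}

#' Paired sign-flip permutation test
#'
#' Two-tailed permutation test of paired values: the per-subject differences
#' are sign-flipped `n_perm` times (the identity flip — the observed data —
#' is always included), and p is the proportion of permuted |mean
#' differences| at least as large as the observed one.
#'
#' @param values_a,values_b Paired numeric vectors (one value per subject).
#' @param n_perm Number of permutations, including the observed one.
#' @param seed Integer seed.
#' @return The two-tailed p value.
#' @export
paired_permutation_test <- function(values_a, values_b, n_perm = 10000L,
                                    seed = 1L) {
  if (length(values_a) != length(values_b)) {
    stop("values_a and values_b must be paired (equal length)")
  }
  n <- length(values_a)
  if (n < 2) stop("permutation test requires >= 2 subjects")
  d <- values_a - values_b
  obs <- mean(d)
  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
  signs[, 1] <- 1 # observed permutation included
  perm_means <- colMeans(d * signs)
  mean(abs(perm_means) >= abs(obs) - 1e-12)
}

#' Pearson correlation with t-based p value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A one-row tibble with `r`, `r_squared`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value, n = length(x))
}

#' Preregistered model predictions
#'
#' The signed TR-10 slope patterns predicted by the three accounts of
#' content/context coding for each of the eight cells (ROI x feature role x
#' item). `"+"` = significantly positive, `"-"` = significantly negative
#' (priority-based remapping), `"0"` = no significant reconstruction.
#'
#' @return A tibble with columns `roi` (`evc`, `ips`), `dimension`
#'   (`content`, `context`), `item` (`pmi`, `umi`) and one column per model:
#'   `domain_dependent`, `functional`, `hybrid`.
#' @export
model_predictions <- function() {
  tibble::tribble(
    ~roi, ~dimension, ~item, ~domain_dependent, ~functional, ~hybrid,
    "evc", "content", "pmi", "+", "+", "+",
    "evc", "context", "pmi", "+", "0", "+",
    "evc", "content", "umi", "0", "-", "0",
    "evc", "context", "umi", "-", "0", "-",
    "ips", "content", "pmi", "+", "0", "+",
    "ips", "context", "pmi", "0", "+", "+",
    "ips", "content", "umi", "-", "0", "-",
    "ips", "context", "umi", "0", "-", "-"
  )
}

#' Adjudicate among the three models
#'
#' Classifies each of the eight preregistered cells (2 ROIs x content/context
#' x PMI/UMI) as significantly positive (`"+"`), significantly negative
#' (`"-"`) or not significant (`"0"`) at `alpha`, and counts matches against
#' each model's predicted pattern.
#'
#' @param cells A tibble with columns `roi` (`"evc"`/`"ips"`), `dimension`
#'   (`"content"`/`"context"`), `item` (`"pmi"`/`"umi"`), `slope` and `p`
#'   (the p values should already carry whatever multiplicity correction the
#'   analysis uses); exactly the 8 cells must be present.
#' @param alpha Significance level for classification.
#' @return An object of class `model_adjudication`: list with `table` (the
#'   cells joined with observed pattern and per-model predictions/matches)
#'   and `match_counts` (named integer vector out of 8).
#' @export
adjudicate_models <- function(cells, alpha = 0.05) {
  req <- model_predictions()[c("roi", "dimension", "item")]
  cells <- tibble::as_tibble(cells)
  missing <- dplyr::anti_join(req, cells, by = c("roi", "dimension", "item"))
  if (nrow(missing) > 0) {
    stop("missing adjudication cell(s): ",
         paste(missing$roi, missing$dimension, missing$item,
               sep = "/", collapse = ", "))
  }
  obs <- dplyr::mutate(
    cells,
    observed = dplyr::case_when(
      .data$p >= alpha ~ "0",
      .data$slope > 0 ~ "+",
      .default = "-"
    )
  )
  tab <- dplyr::left_join(model_predictions(), obs,
                          by = c("roi", "dimension", "item"))
  models <- c("domain_dependent", "functional", "hybrid")
  for (m in models) tab[[paste0(m, "_match")]] <- tab[[m]] == tab$observed
  counts <- vapply(models, function(m) sum(tab[[paste0(m, "_match")]]),
                   integer(1))
  structure(list(table = tab, match_counts = counts, alpha = alpha),
            class = "model_adjudication")
}

#' @export
print.model_adjudication <- function(x, ...) {
  cat("<model_adjudication> matches out of 8 cells (alpha ", x$alpha, "):\n",
      sep = "")
  for (m in names(x$match_counts)) {
    cat("  ", format(m, width = 18), x$match_counts[[m]], "\n")
  }
  invisible(x)
}

#' @rdname adjudicate_models
#' @param x A `model_adjudication`.
#' @param ... Unused.
#' @method tidy model_adjudication
#' @export
tidy.model_adjudication <- function(x, ...) {
  x$table
}

#' @rdname adjudicate_models
#' @method glance model_adjudication
#' @export
glance.model_adjudication <- function(x, ...) {
  tibble::tibble(model = names(x$match_counts),
                 matches = as.integer(x$match_counts),
                 n_cells = 8L, alpha = x$alpha)
}
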