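test_that("collapse-and-slope reproduces hand-computed values", {
  loc_off <- location_basis()$offsets
  # symmetric location curve: collapsed [0, .1, .3, .6, 1] on ranks 0..4
  curve <- c(0, .1, .3, .6, 1, .6, .3, .1, 0)
  expect_equal(reconstruction_slope(curve, loc_off), 0.25)
  # independent least-squares oracle on the collapsed points
  expect_equal(unname(coef(lm(c(0, .1, .3, .6, 1) ~ I(0:4)))[2]), 0.25)
  expect_equal(reconstruction_slope(rep(0.7, 9), loc_off), 0)
  expect_equal(reconstruction_slope(remap_channel_vector(curve), loc_off),
               -0.25)
  # orientation collapsing: 4 points, the +90 channel enters singly
  ori_off <- orientation_basis()$offsets
  cc <- collapse_curve(c(.2, .5, 1, .5, .2, .05), ori_off)
  expect_equal(nrow(cc), 4L)
  expect_equal(cc$abs_offset_deg, c(90, 60, 30, 0))
  expect_equal(cc$response, c(.05, .2, .5, 1))
  expect_error(reconstruction_slope(curve, loc_off + 5), "0-degree")
})

test_that("the slope statistic is linear in the curve", {
  off <- location_basis()$offsets
  set.seed(8)
  for (i in 1:10) {
    curve <- rnorm(9)
    a <- runif(1, -3, 3); b <- runif(1, -2, 2)
    expect_equal(reconstruction_slope(a * curve + b, off),
                 a * reconstruction_slope(curve, off), tolerance = 1e-10)
  }
})

test_that("bootstrap slope test handles degenerate and separated cases", {
  off <- location_basis()$offsets
  peaked <- c(0, .1, .3, .6, 1, .6, .3, .1, 0)
  curves <- matrix(rep(peaked, 10), nrow = 10, byrow = TRUE)
  st <- bootstrap_slope_test(curves, off, n_boot = 1000, seed = 2)
  expect_true(st$p_bound_flag)
  expect_equal(st$p_two_tailed, 2 / 1000)
  expect_equal(st$point_estimate, 0.25)
  # flat curves: all-zero bootstrap distribution reports p = 1
  flat <- matrix(0.3, 6, 9)
  st0 <- bootstrap_slope_test(flat, off, n_boot = 500, seed = 3)
  expect_true(st0$degenerate)
  expect_equal(st0$p_two_tailed, 1)
  # subject order does not change the statistic
  set.seed(9)
  m <- matrix(rnorm(12 * 9), 12, 9)
  s1 <- bootstrap_slope_test(m, off, n_boot = 500, seed = 5)
  s2 <- bootstrap_slope_test(m[12:1, ], off, n_boot = 500, seed = 5)
  expect_equal(s1$point_estimate, s2$point_estimate)
  expect_equal(sort(s1$per_subject_slopes), sort(s2$per_subject_slopes))
})

test_that("bootstrap resampling on slopes equals resampling on curves", {
  off <- orientation_basis()$offsets
  set.seed(10)
  curves <- matrix(rnorm(8 * 6), 8, 6)
  st <- bootstrap_slope_test(curves, off, n_boot = 200, seed = 7)
  # literal path: average resampled curves, then take the slope
  set.seed(7L)
  idx <- matrix(sample.int(8, 8 * 200, replace = TRUE), nrow = 8)
  literal <- vapply(seq_len(200), function(i) {
    reconstruction_slope(colMeans(curves[idx[, i], ]), off)
  }, numeric(1))
  expect_equal(st$boot_distribution, literal, tolerance = 1e-12)
})

test_that("bootstrap difference test respects pairing and tie conventions", {
  off <- location_basis()$offsets
  set.seed(11)
  a <- matrix(rnorm(9 * 9), 9, 9)
  same <- bootstrap_difference_test(a, a, off, n_boot = 400, seed = 1)
  expect_true(same$degenerate)
  expect_equal(same$p_two_tailed, 1)
  shift <- a + matrix(rep(c(0, .2, .4, .6, 1, .6, .4, .2, 0), each = 9), 9, 9)
  sep <- bootstrap_difference_test(shift, a, off, n_boot = 400, seed = 1)
  expect_true(sep$p_bound_flag)
  expect_equal(sep$p_two_tailed, 2 / 400)
  expect_error(bootstrap_difference_test(a, a[1:5, ], off), "paired")
})

test_that("adding a positive offset to every curve never increases the p value", {
  off <- location_basis()$offsets
  set.seed(12)
  base <- matrix(rnorm(10 * 9, sd = 0.5), 10, 9)
  bump <- matrix(rep(c(0, 0, .1, .3, 1, .3, .1, 0, 0), each = 10), 10, 9)
  ps <- vapply(c(0, 0.5, 1, 2, 4), function(g) {
    bootstrap_slope_test(base + g * bump, off, n_boot = 1000,
                         seed = 20)$p_two_tailed
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("Benjamini-Hochberg mask matches a brute-force step-up oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(fdr_bh(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_true(fdr_bh(0.04, 0.05))
  expect_error(fdr_bh(c(0.1, 0.2), q = 1.2), "q must be")
  expect_error(fdr_bh(c(0.1, 1.4)), "p values")
  step_up_oracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    k <- max(c(0L, which(p[ord] <= q * seq_len(m) / m)))
    rej <- logical(m)
    if (k > 0) rej[ord[seq_len(k)]] <- TRUE
    rej
  }
  set.seed(13)
  for (i in 1:25) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p, 0.05), step_up_oracle(p, 0.05))
  }
})

test_that("exact noncentral-t power search gives the standard cohort size", {
  expect_equal(required_sample_size(0.62, 0.90, 0.05, "one"), 24L)
  # defining property at the boundary
  pw <- function(n, d = 0.62, a = 0.05) {
    1 - pt(qt(1 - a, n - 1), n - 1, ncp = d * sqrt(n))
  }
  expect_gte(pw(24), 0.90)
  expect_lt(pw(23), 0.90)
  # independent oracle for a different effect size
  n2 <- required_sample_size(2.0, 0.90, 0.05, "one")
  oracle <- ceiling(power.t.test(delta = 2.0, sd = 1, sig.level = 0.05,
                                 power = 0.90, type = "one.sample",
                                 alternative = "one.sided")$n)
  expect_equal(n2, oracle)
  # two-tailed values agree with power.t.test as well
  n3 <- required_sample_size(0.5, 0.80, 0.05, "two")
  oracle3 <- ceiling(power.t.test(delta = 0.5, sd = 1, sig.level = 0.05,
                                  power = 0.80, type = "one.sample",
                                  alternative = "two.sided")$n)
  expect_equal(n3, oracle3)
})

test_that("paired permutation test respects its tie and extremity conventions", {
  expect_equal(paired_permutation_test(rep(2, 10), rep(2, 10), 500), 1)
  p <- paired_permutation_test(rep(5, 24), rep(0, 24), n_perm = 2000, seed = 4)
  expect_lte(p, 0.01)
  expect_error(paired_permutation_test(1:4, 1:5), "paired")
})

test_that("pearson correlation matches the direct formula", {
  pc <- pearson_correlation(1:10, 2 * (1:10) + 1)
  expect_equal(pc$r, 1)
  expect_equal(pc$r_squared, 1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  direct_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pc2 <- pearson_correlation(x, y)
  expect_equal(pc2$r_squared, direct_r^2, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
})

test_that("model adjudication counts matches against each prediction table", {
  preds <- model_predictions()
  # a pattern identical to the functional model matches it 8/8
  cells <- dplyr::mutate(
    preds[c("roi", "dimension", "item")],
    slope = dplyr::case_when(preds$functional == "+" ~ 0.2,
                             preds$functional == "-" ~ -0.2,
                             .default = 0.01),
    p = ifelse(preds$functional == "0", 0.6, 0.001)
  )
  adj <- adjudicate_models(cells, alpha = 0.05)
  expect_equal(unname(adj$match_counts["functional"]), 8L)
  # the observed early-visual pattern: content +/+ (PMI/UMI), context 0/0 —
  # functional matches 3 of the 4 cells (it predicted negative UMI content)
  evc <- adj$table[adj$table$roi == "evc", ]
  obs <- c("+", "0", "+", "0")[match(paste(evc$dimension, evc$item),
                                     c("content pmi", "context pmi",
                                       "content umi", "context umi"))]
  cells2 <- cells
  cells2$slope[cells2$roi == "evc"] <- ifelse(obs == "+", 0.2, 0.01)
  cells2$p[cells2$roi == "evc"] <- ifelse(obs == "+", 0.001, 0.6)
  adj2 <- adjudicate_models(cells2, alpha = 0.05)
  f_evc <- adj2$table[adj2$table$roi == "evc", "functional_match", drop = TRUE]
  expect_equal(sum(f_evc), 3L)
  # all-null pattern: each model matches exactly its predicted-0 cells
  cells0 <- cells
  cells0$p <- 1
  adj0 <- adjudicate_models(cells0, alpha = 0.05)
  expect_equal(unname(adj0$match_counts),
               c(sum(preds$domain_dependent == "0"),
                 sum(preds$functional == "0"),
                 sum(preds$hybrid == "0")))
  expect_equal(unname(adj0$match_counts["hybrid"]), 1L)
  expect_error(adjudicate_models(cells[-1, ]), "missing")
})
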