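#' Estimate encoding-model weights
#'
#' Trains the linear encoding model \eqn{B_1 = W C_1} by ordinary least
#' squares, using the closed form
#' \eqn{\hat{W} = B_1 C_1^T (C_1 C_1^T)^{-1}}: each voxel's weight row is the
#' least-squares projection of its responses onto the idealized channel
#' responses.
#'
#' @param B1 Training data, `v voxels x n trials` numeric matrix.
#' @param C1 Idealized channel responses, `k channels x n trials` (from
#'   [ideal_channel_matrix()]).
#' @param label Name of the feature dimension, used in error messages.
#' @return The `v x k` estimated weight matrix.
#' @export
estimate_weights <- function(B1, C1, label = "feature") {
  B1 <- as.matrix(B1); C1 <- as.matrix(C1)
  if (ncol(B1) != ncol(C1)) stop("B1 and C1 must have the same number of trials")
  k <- nrow(C1)
  if (ncol(C1) < k) {
    stop("rank-deficient ", label, " channel matrix: ", ncol(C1),
         " trials for ", k, " channels")
  }
  CCt <- C1 %*% t(C1)
  if (rcond(CCt) < 1e-10) {
    stop("rank-deficient ", label, " channel matrix: C1 %*% t(C1) is ",
         "(near-)singular; training trials do not span the channel space")
  }
  B1 %*% t(C1) %*% solve(CCt)
}

#' Invert an encoding model on new data
#'
#' Applies the inversion step
#' \eqn{\hat{C}_2 = (\hat{W}^T \hat{W})^{-1} \hat{W}^T B_2}: the reconstructed
#' channel responses are the least-squares solution of \eqn{B_2 = \hat{W} C_2}
#' for the held-out data.
#'
#' @param W A `v x k` weight matrix from [estimate_weights()].
#' @param B2 Test data, `v x n` matrix.
#' @return The `k x n` reconstructed channel-response matrix.
#' @export
invert_model <- function(W, B2) {
  W <- as.matrix(W); B2 <- as.matrix(B2)
  if (nrow(W) < ncol(W)) {
    stop("underdetermined inversion: ", nrow(W), " voxels for ", ncol(W),
         " channels")
  }
  if (nrow(B2) != nrow(W)) stop("B2 must have one row per voxel of W")
  WtW <- crossprod(W)
  if (rcond(WtW) < 1e-10) {
    stop("singular weight matrix: t(W) %*% W is (near-)singular")
  }
  solve(WtW, crossprod(W, B2))
}

#' Recenter reconstructions to a common 0-degree channel
#'
#' Circularly shifts each trial's reconstructed channel vector by an integer
#' number of channels so that the channel nearest the trial's feature label
#' lands at the basis's designated 0-degree-offset position. The multiset of
#' values in each trial's vector is preserved (a pure permutation); residual
#' sub-channel jitter in the labels is ignored.
#'
#' @param recon `k x n` reconstructed channel responses.
#' @param labels Feature label per trial (length n), degrees.
#' @param basis The [channel_basis()] the reconstruction lives in.
#' @return A `k x n` matrix of recentered reconstructions; row i corresponds
#'   to channel offset `basis$offsets[i]` degrees.
#' @export
recenter_reconstruction <- function(recon, labels, basis) {
  recon <- as.matrix(recon)
  stopifnot(inherits(basis, "channel_basis"), nrow(recon) == basis$n_channels)
  if (length(labels) != ncol(recon)) stop("one label per trial required")
  if (any(!is.finite(labels))) stop("labels must be finite")
  k <- basis$n_channels
  nearest <- nearest_channel(basis, labels)
  out <- recon
  for (j in seq_len(ncol(recon))) {
    idx <- ((seq_len(k) - basis$zero_pos + nearest[j] - 1L) %% k) + 1L
    out[, j] <- recon[idx, j]
  }
  rownames(out) <- basis$offsets
  out
}

# index of the channel whose center is circularly nearest each label
nearest_channel <- function(basis, labels) {
  d <- abs(outer(basis$centers, wrap_angle(labels, basis$period),
                 function(c, f) wrap_signed(f - c, basis$period)))
  apply(d, 2, which.min)
}

#' Leave-one-run-out reconstruction time course
#'
#' For each requested TR and each held-out run, trains the encoding model on
#' all other runs at that TR (training labels are always the prioritized
#' item's feature), inverts it on the held-out run at the same TR, and
#' recenters each test trial's reconstruction to the label of the requested
#' test item (PMI or UMI). Every trial appears exactly once as test data.
#'
#' @param dataset A `bold_dataset` (typically after [zscore_runs()]).
#' @param feature_dim `"location"` or `"orientation"`.
#' @param test_item `"pmi"` or `"umi"` — whose labels are used to recenter
#'   the test reconstructions (training is always on PMI labels).
#' @param trs Integer TR indices to reconstruct (default all 12).
#' @return An object of class `iem_recon`: list with `mean_curves`
#'   (`length(trs) x k` matrix of trial-averaged recentered responses, rows
#'   named by TR), `per_trial` (`k x n_trials x length(trs)` array),
#'   `offsets`, `basis`, `feature_dim`, `item`, `trs`.
#' @export
crossval_reconstruct_timecourse <- function(dataset,
                                            feature_dim = c("location", "orientation"),
                                            test_item = c("pmi", "umi"),
                                            trs = 1:12) {
  stopifnot(inherits(dataset, "bold_dataset"))
  feature_dim <- match.arg(feature_dim)
  test_item <- match.arg(test_item)
  n_runs <- dim(dataset$data)[1]
  if (n_runs < 2) stop("leave-one-run-out cross-validation needs >= 2 runs")
  basis <- if (feature_dim == "location") location_basis() else orientation_basis()
  feats <- item_features(dataset$design)
  train_labels <- feats[[paste0("pmi_", substr(feature_dim, 1, 3))]]
  test_labels <- feats[[paste0(test_item, "_", substr(feature_dim, 1, 3))]]
  run_of <- dataset$design$run
  n_trials <- nrow(dataset$design)
  k <- basis$n_channels

  C_all <- ideal_channel_matrix(basis, train_labels)
  per_trial <- array(NA_real_, dim = c(k, n_trials, length(trs)),
                     dimnames = list(basis$offsets, NULL, trs))
  for (ti in seq_along(trs)) {
    tr <- trs[ti]
    B_all <- get_tr_matrix(dataset, tr)
    for (r in seq_len(n_runs)) {
      test_idx <- which(run_of == r)
      train_idx <- which(run_of != r)
      W <- tryCatch(
        estimate_weights(B_all[, train_idx, drop = FALSE],
                         C_all[, train_idx, drop = FALSE],
                         label = feature_dim),
        error = function(e) stop("fold (held-out run ", r, "), TR ", tr,
                                 ": ", conditionMessage(e), call. = FALSE)
      )
      C2 <- invert_model(W, B_all[, test_idx, drop = FALSE])
      per_trial[, test_idx, ti] <-
        recenter_reconstruction(C2, test_labels[test_idx], basis)
    }
  }
  mean_curves <- t(apply(per_trial, 3, rowMeans))
  dimnames(mean_curves) <- list(trs, basis$offsets)
  structure(
    list(mean_curves = mean_curves, per_trial = per_trial,
         offsets = basis$offsets, basis = basis, feature_dim = feature_dim,
         item = test_item, trs = trs),
    class = "iem_recon"
  )
}

#' @export
print.iem_recon <- function(x, ...) {
  cat("<iem_recon> ", x$feature_dim, " / ", toupper(x$item), ", TRs ",
      paste(range(x$trs), collapse = "-"), ", ", x$basis$n_channels,
      " channels\n", sep = "")
  invisible(x)
}

#' Tidy an IEM reconstruction
#'
#' @param x An `iem_recon`.
#' @param ... Unused.
#' @return A tibble with columns `tr`, `channel_offset_deg`, `response`
#'   (trial-averaged recentered channel response).
#' @method tidy iem_recon
#' @export
tidy.iem_recon <- function(x, ...) {
  tibble::tibble(
    tr = rep(x$trs, times = length(x$offsets)),
    channel_offset_deg = rep(x$offsets, each = length(x$trs)),
    response = as.vector(x$mean_curves)
  ) |> dplyr::arrange(.data$tr, .data$channel_offset_deg)
}

#' Export reconstructions in long format
#'
#' Writes the trial-averaged reconstruction as a TSV with columns `subject`,
#' `roi`, `feature_dim`, `item`, `tr`, `channel_offset_deg`, `response`.
#'
#' @param recon An `iem_recon`.
#' @param path Output TSV path.
#' @param subject,roi Identifiers recorded in the table.
#' @return `path`, invisibly.
#' @export
write_reconstruction <- function(recon, path, subject = 1L, roi = "roi") {
  out <- tidy.iem_recon(recon)
  out <- tibble::add_column(out, subject = subject, roi = roi,
                            feature_dim = recon$feature_dim,
                            item = recon$item, .before = 1)
  readr::write_tsv(out, path)
  invisible(path)
}
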