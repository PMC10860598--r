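#' Circular tuning-channel basis
#'
#' Constructs a basis of idealized feature-tuned channels on a circular
#' feature space. Each channel's tuning curve is a half-wave-rectified
#' sinusoid raised to an integer power, the standard inverted-encoding-model
#' (IEM) basis: the activation of a channel centered at \eqn{c} for a feature
#' \eqn{x} is \eqn{\max(0, \cos(\pi \Delta / P))^p}, where \eqn{\Delta} is the
#' signed circular difference \eqn{x - c} wrapped to \eqn{(-P/2, P/2]} and
#' \eqn{P} is the period of the space. One half-cycle of the rectified
#' sinusoid spans the full feature period, so the activation is 1 at the
#' channel center and falls to 0 at half a period away.
#'
#' @param period Period of the circular feature space in degrees (360 for
#'   polar-angle location, 180 for bar orientation).
#' @param centers Ordered channel centers in degrees; must be strictly
#'   increasing and equally spaced with spacing `period / length(centers)`.
#' @param exponent Integer power \eqn{p \ge 1} applied after rectification.
#'
#' @return An object of class `channel_basis`: a list with elements `period`,
#'   `centers`, `exponent`, `n_channels`, `zero_pos` (index of the channel
#'   used as the common 0-degree center after recentering) and `offsets`
#'   (signed channel offsets in degrees relative to that channel).
#' @seealso [location_basis()], [orientation_basis()], [channel_response()]
#' @export
#' @examples
#' b <- location_basis()
#' channel_response(b, 20)
channel_basis <- function(period, centers, exponent) {
  stopifnot(is.numeric(period), length(period) == 1L, period > 0)
  stopifnot(is.numeric(centers), length(centers) >= 2L)
  stopifnot(is.numeric(exponent), length(exponent) == 1L, exponent >= 1)
  k <- length(centers)
  spacing <- period / k
  if (any(diff(centers) <= 0)) {
    stop("channel centers must be strictly increasing")
  }
  if (max(abs(diff(centers) - spacing)) > 1e-9) {
    stop("channel centers must be equally spaced at period / n_channels = ",
         spacing, " degrees")
  }
  # common center after recentering: middle channel for odd k, k/2 for even k,
  # so that the offset grid matches the experiment's signed distance sets
  zero_pos <- if (k %% 2L == 1L) (k + 1L) %/% 2L else k %/% 2L
  offsets <- wrap_signed(centers - centers[zero_pos], period)
  structure(
    list(period = period, centers = as.numeric(centers),
         exponent = as.integer(exponent), n_channels = k,
         zero_pos = zero_pos, offsets = offsets),
    class = "channel_basis"
  )
}

#' @export
print.channel_basis <- function(x, ...) {
  cat("<channel_basis> ", x$n_channels, " channels, period ", x$period,
      " deg, exponent ", x$exponent, "\n", sep = "")
  cat("  centers:", paste(x$centers, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname channel_basis
#' @details `location_basis()` returns the 9-channel polar-angle basis
#'   (centers 20, 60, ..., 340 degrees; exponent 8) and `orientation_basis()`
#'   the 6-channel orientation basis (centers 15, 45, ..., 165 degrees;
#'   exponent 6) used throughout the DSR analysis.
#' @export
location_basis <- function() {
  channel_basis(360, seq(20, 340, by = 40), 8L)
}

#' @rdname channel_basis
#' @export
orientation_basis <- function() {
  channel_basis(180, seq(15, 165, by = 30), 6L)
}

#' Wrap angles
#'
#' `wrap_angle()` wraps into `[0, period)`; `wrap_signed()` wraps a signed
#' difference into `(-period/2, period/2]`.
#'
#' @param x Numeric angles or differences, degrees.
#' @param period Period of the circular space, degrees.
#' @return Numeric vector of the same length.
#' @keywords internal
#' @export
wrap_angle <- function(x, period) {
  x %% period
}

#' @rdname wrap_angle
#' @export
wrap_signed <- function(x, period) {
  h <- period / 2
  w <- (x + h) %% period - h
  # map -period/2 to +period/2 so the interval is (-P/2, P/2]
  w[abs(w + h) < 1e-9] <- h
  w
}

#' Channel activations for a feature value
#'
#' Evaluates every channel's rectified-sinusoid tuning function at one or more
#' feature values.
#'
#' @param basis A [channel_basis()].
#' @param feature Feature value(s) in degrees; wrapped into the basis period.
#' @return For a single feature, a numeric vector of length `n_channels`; for
#'   `n` features, an `n_channels x n` matrix (one column per feature).
#' @export
channel_response <- function(basis, feature) {
  stopifnot(inherits(basis, "channel_basis"))
  if (!is.numeric(feature) || any(!is.finite(feature))) {
    stop("feature values must be finite numerics")
  }
  delta <- outer(basis$centers, wrap_angle(feature, basis$period),
                 function(c, f) wrap_signed(f - c, basis$period))
  act <- pmax(0, cos(pi * delta / basis$period))^basis$exponent
  if (length(feature) == 1L) drop(act) else act
}

#' Idealized channel-response matrix
#'
#' Builds the k-channels-by-n-trials matrix of idealized channel responses
#' used as the regressor matrix when training an encoding model: column i is
#' the channel activation vector for trial i's feature label.
#'
#' @param basis A [channel_basis()].
#' @param labels Feature value per trial, degrees (length n >= 1).
#' @return A `k x n` numeric matrix with rownames giving channel centers.
#' @export
ideal_channel_matrix <- function(basis, labels) {
  stopifnot(inherits(basis, "channel_basis"))
  if (length(labels) < 1L) stop("labels must contain at least one trial")
  m <- channel_response(basis, labels)
  m <- matrix(m, nrow = basis$n_channels)
  rownames(m) <- basis$centers
  m
}
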