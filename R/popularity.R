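#' Weekly popularity matrix
#'
#' Validates and classes a 7x24 matrix of relative popularity values in the
#' Popular Times convention: rows are days of week (Monday first), columns
#' are local clock hours 0--23, entries are integers from 0 (closed / unused)
#' to 100 (the busiest hour of the whole week).
#'
#' @param values a 7x24 numeric matrix (or object coercible to one) of
#'   integers in `[0, 100]`.
#' @return a `weekly_popularity` object (a 7x24 matrix with day/hour
#'   dimnames).
#' @examples
#' w <- weekly_popularity(matrix(50L, 7, 24))
#' mean_daily(w)
#' @export
weekly_popularity <- function(values) {
  values <- try(as.matrix(values), silent = TRUE)
  if (inherits(values, "try-error") || !is.numeric(values)) {
    pa_stop_structural("weekly popularity must be a numeric 7x24 matrix")
  }
  if (!identical(dim(values), c(7L, 24L))) {
    pa_stop_structural(sprintf(
      "weekly popularity must be 7x24 (got %dx%d)", nrow(values), ncol(values)
    ))
  }
  if (!all(is.finite(values))) {
    pa_stop_structural("weekly popularity contains non-finite values")
  }
  if (any(values < 0 | values > 100)) {
    pa_stop_structural("weekly popularity values must lie in [0, 100]")
  }
  if (any(abs(values - round(values)) > 1e-8)) {
    pa_stop_structural("weekly popularity values must be integers")
  }
  values <- round(values)
  dimnames(values) <- list(
    day = c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
            "Saturday", "Sunday"),
    hour = 0:23
  )
  structure(values, class = c("weekly_popularity", "matrix", "array"))
}

#' Mean daily popularity vector
#'
#' Collapses a weekly popularity matrix to a single 24-hour profile by
#' averaging each hour across the seven days of the week. This is the
#' per-establishment vector that enters the activation distribution.
#'
#' @param weekly a [weekly_popularity()] object or valid 7x24 matrix.
#' @return numeric vector of length 24, named by hour; entries are
#'   non-negative reals.
#' @export
mean_daily <- function(weekly) {
  if (!inherits(weekly, "weekly_popularity")) weekly <- weekly_popularity(weekly)
  out <- colMeans(unclass(weekly))
  names(out) <- 0:23
  out
}

check_dailies <- function(dailies) {
  if (is.numeric(dailies) && is.null(dim(dailies))) dailies <- list(dailies)
  if (is.matrix(dailies)) dailies <- asplit(dailies, 1)
  if (!is.list(dailies) || length(dailies) == 0L) {
    pa_stop_structural("need at least one daily popularity vector")
  }
  m <- vapply(dailies, function(d) {
    if (!is.numeric(d) || length(d) != 24L) {
      pa_stop_structural("each daily popularity vector must be numeric of length 24")
    }
    if (!all(is.finite(d)) || any(d < 0)) {
      pa_stop_structural("daily popularity values must be finite and non-negative")
    }
    as.numeric(d)
  }, numeric(24))
  t(m) # n x 24
}

#' Daily activation distribution of a set of establishments
#'
#' Pools the mean daily popularity vectors of all establishments in a buffer
#' and normalizes over the 24-hour day: entry `h` is the estimated
#' conditional probability that a visitor to any establishment in the buffer
#' on an average day is there during hour `h`.
#'
#' @param dailies the mean daily popularity vectors: a list of length-24
#'   non-negative numeric vectors, an `n x 24` matrix, or a single vector.
#' @return an `activation_distribution`: numeric length-24 probability
#'   vector summing to 1, named by hour.
#' @seealso [mean_daily()], [l2_norm()]
#' @export
activation_distribution <- function(dailies) {
  m <- check_dailies(dailies)
  hourly <- colSums(m)
  total <- sum(hourly)
  if (total <= 0) {
    pa_stop_degenerate(
      "total popularity is zero: no measurable activation in this buffer"
    )
  }
  probs <- hourly / total
  names(probs) <- 0:23
  structure(probs, class = "activation_distribution")
}

check_distribution <- function(dist) {
  if (!is.numeric(dist) || length(dist) != 24L) {
    pa_stop_structural("activation distribution must be numeric of length 24")
  }
  if (!all(is.finite(dist)) || any(dist < -1e-12)) {
    pa_stop_structural("activation distribution entries must be non-negative")
  }
  if (abs(sum(dist) - 1) > 1e-9) {
    pa_stop_structural("activation distribution must sum to 1 (within 1e-9)")
  }
  as.numeric(dist)
}

#' L2 norm of an activation distribution
#'
#' The Euclidean norm of the 24-hour activation probability vector,
#' `sqrt(sum(p_h^2))`. It ranges from `1/sqrt(24) = 0.204` for perfectly
#' even activation across the day up to 1 when all activation is
#' concentrated in a single hour; larger values mean a less even temporal
#' distribution of neighborhood activation.
#'
#' @param dist an [activation_distribution()] (length-24 probability vector).
#' @return a real number in `[1/sqrt(24), 1]`.
#' @examples
#' l2_norm(activation_distribution(rep(1, 24)))      # 1/sqrt(24)
#' l2_norm(activation_distribution(c(5, rep(0, 23)))) # 1
#' @export
l2_norm <- function(dist) {
  p <- check_distribution(dist)
  sqrt(sum(p * p))
}

#' Windowed L2 norm (sensitivity variant)
#'
#' Rebuilds the activation distribution using only the hours in
#' `[start_hour, end_hour]` (inclusive) and returns its L2 norm. By default
#' the denominator is renormalized over the window, so the result is the L2
#' norm of a proper distribution over `end_hour - start_hour + 1` hours and
#' the lower bound `1/sqrt(k)` retains its uniform-activation meaning. With
#' `renormalize = FALSE` the full-day total is kept as denominator and the
#' norm is taken of the (sub-stochastic) windowed mass.
#'
#' @param dailies as in [activation_distribution()].
#' @param start_hour,end_hour window bounds, local hours with
#'   `0 <= start_hour <= end_hour <= 23`. Defaults 9 and 19 (the 9am hour
#'   through the 7pm hour).
#' @param renormalize logical; renormalize within the window (default TRUE).
#' @return a real number; with renormalization, in `[1/sqrt(k), 1]` where
#'   `k` is the window width in hours.
#' @export
l2_norm_windowed <- function(dailies, start_hour = 9, end_hour = 19,
                             renormalize = TRUE) {
  if (!is.numeric(start_hour) || !is.numeric(end_hour) ||
      length(start_hour) != 1L || length(end_hour) != 1L ||
      start_hour != round(start_hour) || end_hour != round(end_hour) ||
      start_hour < 0 || end_hour > 23 || start_hour > end_hour) {
    pa_stop_structural("window hours must satisfy 0 <= start_hour <= end_hour <= 23")
  }
  m <- check_dailies(dailies)
  hourly <- colSums(m)
  win <- hourly[(start_hour:end_hour) + 1L]
  if (sum(win) <= 0) {
    pa_stop_degenerate("window contains no popularity mass")
  }
  denom <- if (renormalize) sum(win) else sum(hourly)
  p <- win / denom
  sqrt(sum(p * p))
}

#' Buffer-level L2 norm from establishment daily profiles
#'
#' Convenience composition of [activation_distribution()] and [l2_norm()].
#'
#' @inheritParams activation_distribution
#' @return the L2 norm of the pooled activation distribution.
#' @export
park_l2 <- function(dailies) {
  l2_norm(activation_distribution(dailies))
}
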