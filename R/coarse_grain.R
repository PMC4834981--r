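#' Coarse-grain a series at scale tau with a selected moment
#'
#' Divides the source series into non-overlapping, left-aligned segments of
#' `scale` consecutive points (any trailing remainder shorter than `scale`
#' is discarded) and summarises each segment with one statistical moment:
#' the mean, the unbiased sample variance (denominator `scale - 1`), or the
#' bias-adjusted sample skewness. The resulting sequence is the
#' coarse-grained series at scale factor `scale`; at `scale = 1` with
#' `moment = "mean"` it equals the source series.
#'
#' Units: mean values carry the source units, variance values the source
#' units squared (seconds squared for RR input), skewness is dimensionless.
#'
#' @param series numeric vector or [rr_series()].
#' @param scale positive integer segment length (tau). `moment = "variance"`
#'   requires `scale >= 2`; `"skewness"` requires `scale >= 3`.
#' @param moment `"mean"`, `"variance"` or `"skewness"`.
#' @return An object of class `coarse_grained`: list with `values`, `scale`,
#'   `moment` and `n_source`.
#' @examples
#' coarse_grain(c(0, 1, 0, 1, 0, 1), scale = 2, moment = "variance")$values
#' @export
coarse_grain <- function(series, scale, moment = c("mean", "variance", "skewness")) {
  moment <- match.arg(moment)
  x <- series_values(series)
  min_scale <- c(mean = 1L, variance = 2L, skewness = 3L)[[moment]]
  if (!is_count(scale, min = 1L)) {
    stop_validation("scale must be a positive integer (got %s)", format(scale))
  }
  scale <- as.integer(scale)
  if (scale < min_scale) {
    stop_validation("moment '%s' requires scale >= %d (got %d)",
                    moment, min_scale, scale)
  }
  n <- length(x)
  if (n < scale) {
    stop_validation("series of length %d is shorter than one segment of %d points",
                    n, scale)
  }
  if (!all(is.finite(x))) stop_validation("series contains non-finite values")

  nseg <- n %/% scale
  vals <- if (scale == 1L) {
    switch(moment, mean = x,
           stop_validation("moment '%s' requires scale >= %d", moment, min_scale))
  } else {
    m <- matrix(x[seq_len(nseg * scale)], nrow = scale)
    switch(moment,
      mean = colMeans(m),
      variance = segment_variance(m),
      skewness = apply(m, 2L, sample_skewness))
  }
  structure(list(values = as.numeric(vals), scale = scale, moment = moment,
                 n_source = n),
            class = "coarse_grained")
}

# Unbiased per-segment variance, columns of m are segments. Two-pass
# (centered) form to avoid cancellation on small-variance RR data.
segment_variance <- function(m) {
  tau <- nrow(m)
  cm <- colMeans(m)
  colSums((m - rep(cm, each = tau))^2) / (tau - 1)
}

# Bias-adjusted (Fisher-Pearson) sample skewness,
# G1 = g1 * sqrt(n (n - 1)) / (n - 2) with g1 = m3 / m2^(3/2).
sample_skewness <- function(x) {
  n <- length(x)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  g1 <- mean(d^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' @export
print.coarse_grained <- function(x, ...) {
  cat(sprintf("coarse-grained series: moment = %s, scale = %d, %d segments (from %d points)\n",
              x$moment, x$scale, length(x$values), x$n_source))
  invisible(x)
}

#' Moving-window moment of a series (display helper)
#'
#' Computes the selected moment in a sliding window of stride 1. This is a
#' visualisation aid for inspecting, e.g., the local variance (volatility)
#' of an RR series alongside the raw intervals; it is *not* the
#' coarse-graining used by [mse_curve()], which summarises non-overlapping
#' segments.
#'
#' @param series numeric vector or [rr_series()].
#' @param window window length; `>= 2` for variance, `>= 3` for skewness.
#' @param moment `"mean"`, `"variance"` or `"skewness"`.
#' @return Numeric vector of length `length(series) - window + 1`.
#' @export
rolling_moment <- function(series, window, moment = c("mean", "variance", "skewness")) {
  moment <- match.arg(moment)
  x <- series_values(series)
  min_w <- c(mean = 1L, variance = 2L, skewness = 3L)[[moment]]
  if (!is_count(window, min = min_w)) {
    stop_validation("window must be an integer >= %d for moment '%s'", min_w, moment)
  }
  window <- as.integer(window)
  n <- length(x)
  if (n < window) {
    stop_validation("window of %d points exceeds series length %d", window, n)
  }
  nout <- n - window + 1L
  if (moment == "skewness") {
    return(vapply(seq_len(nout),
                  function(k) sample_skewness(x[k:(k + window - 1L)]),
                  numeric(1L)))
  }
  # running sums on the globally centered series (shift-invariant moments)
  xc <- x - mean(x)
  cs <- c(0, cumsum(xc))
  s1 <- cs[(window + 1L):(n + 1L)] - cs[seq_len(nout)]
  if (moment == "mean") return(s1 / window + mean(x))
  cs2 <- c(0, cumsum(xc^2))
  s2 <- cs2[(window + 1L):(n + 1L)] - cs2[seq_len(nout)]
  pmax((s2 - s1^2 / window) / (window - 1), 0)
}
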