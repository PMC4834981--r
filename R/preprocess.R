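#' Parameters for the moving-window RR artifact filter
#'
#' @param l window length in data points; odd integer, at least 3.
#'   Default 41, the value conventionally used for 24-h Holter RR series.
#' @param a relative tolerance, dimensionless, `0 < a <= 1`. Default 0.2:
#'   a beat is rejected when it deviates from its local mean by more
#'   than 20 percent.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(l = 41L, a = 0.2) {
  if (!is_count(l, min = 3L) || l %% 2L == 0L) {
    stop_validation("window length l must be an odd integer >= 3 (got %s)",
                    format(l))
  }
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0 || a > 1) {
    stop_validation("tolerance a must satisfy 0 < a <= 1 (got %s)", format(a))
  }
  structure(list(l = as.integer(l), a = as.numeric(a)), class = "filter_params")
}

#' Moving-window artifact filter for RR-interval series
#'
#' Excludes artifacts, premature ventricular complexes and missed beat
#' detections from an RR series. For each point, the mean of the other
#' points in a window of length `l` centered on it is computed from the
#' original series; the point is excluded when it lies outside
#' `[(1 - a) * mean, (1 + a) * mean]`. Surviving points are concatenated in
#' order. The criterion is relative, so rescaling the whole series leaves
#' the excluded set unchanged.
#'
#' Decisions are made against the original series in a single pass by
#' default; `iterate = TRUE` repeats the pass on the surviving points until
#' no further exclusions occur. Edge points without a full centered window
#' are evaluated against a truncated window (all available neighbours
#' within `(l - 1) / 2` on each side, center excluded) when
#' `edges = "truncated"` (default), or never excluded when `edges = "keep"`.
#' Series shorter than `l` but with at least 3 points fall back to
#' truncated-window evaluation throughout.
#'
#' @param series an [rr_series()] or numeric vector.
#' @param params a [filter_params()] object.
#' @param edges `"truncated"` or `"keep"` (see Details).
#' @param iterate repeat filtering passes until stable? Default `FALSE`.
#' @return An [rr_series()] of surviving intervals whose `filter_report`
#'   field records `n_input`, `n_excluded` and the sorted (1-based)
#'   `excluded_indices` into the input series.
#' @examples
#' x <- rep(0.8, 100); x[51] <- 1.6
#' f <- filter_rr(rr_series(x), filter_params(l = 41, a = 0.2))
#' f$filter_report$excluded_indices   # 51
#' @export
filter_rr <- function(series, params = filter_params(),
                      edges = c("truncated", "keep"), iterate = FALSE) {
  edges <- match.arg(edges)
  if (!inherits(params, "filter_params")) {
    params <- do.call(filter_params, as.list(params))
  }
  x0 <- series_values(series)
  label <- if (inherits(series, "rr_series")) series$label else "rr"
  n0 <- length(x0)
  if (n0 < 3L) stop_validation("series too short to filter: need >= 3 points, got %d", n0)
  if (edges == "keep" && n0 < params$l) {
    stop_validation("series of length %d has no full window of length %d; use edges = 'truncated'",
                    n0, params$l)
  }

  excluded <- integer(0)
  keep_idx <- seq_len(n0)
  x <- x0
  repeat {
    drop <- filter_pass(x, params$l, params$a, edges)
    if (length(drop) > 0L) excluded <- c(excluded, keep_idx[drop])
    if (!iterate || length(drop) == 0L) break
    keep_idx <- keep_idx[-drop]
    x <- x[-drop]
    if (length(x) < 3L) break
  }
  excluded <- sort(excluded)
  report <- structure(list(n_input = n0, n_excluded = length(excluded),
                           excluded_indices = excluded,
                           params = params, edges = edges,
                           iterated = isTRUE(iterate)),
                      class = "filter_report")
  out <- if (length(excluded) > 0L) x0[-excluded] else x0
  if (length(out) == 0L) {
    stop_validation("filter excluded every point; check parameters (l = %d, a = %g)",
                    params$l, params$a)
  }
  rr_series(out, label = label,
            sampling_note = if (inherits(series, "rr_series")) series$sampling_note,
            filter_report = report)
}

# One filtering pass: indices (into x) failing the relative-deviation
# criterion. Window means (center excluded) come from running sums, so a
# pass is O(n) regardless of l.
filter_pass <- function(x, l, a, edges) {
  n <- length(x)
  h <- (l - 1L) %/% 2L
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h)
  hi <- pmin(n, idx + h)
  cs <- c(0, cumsum(x))
  wsum <- cs[hi + 1L] - cs[lo] - x
  cnt <- hi - lo                      # neighbours in window, center excluded
  evaluable <- cnt >= h                # truncated windows need >= (l-1)/2 neighbours
  if (edges == "keep") evaluable <- (idx - h >= 1L) & (idx + h <= n)
  m <- wsum / cnt
  bad <- evaluable & (x < (1 - a) * m | x > (1 + a) * m)
  which(bad)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("RR artifact filter (l = %d, a = %g, edges = %s%s): %d of %d excluded (%.2f%%)\n",
              x$params$l, x$params$a, x$edges,
              if (x$iterated) ", iterated" else "",
              x$n_excluded, x$n_input, 100 * x$n_excluded / x$n_input))
  invisible(x)
}
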