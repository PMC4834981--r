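#' Sample entropy parameters
#'
#' Bundles the template length `m` and the tolerance convention used to
#' resolve the absolute match threshold `r`. Three conventions are
#' supported:
#' \describe{
#'   \item{`percent_of_sd`}{`r` is a percentage of the standard deviation
#'     of the original (post-filter) series, resolved once by [resolve_r()]
#'     and then held constant across all scales. This is the default; the
#'     conventional values are `r_value = 15` for mean coarse-graining and
#'     `r_value = 0.5` for variance coarse-graining, the latter much
#'     smaller because variance coarse-grained amplitudes are much smaller
#'     than mean coarse-grained ones.}
#'   \item{`fixed_absolute`}{`r_value` *is* the tolerance, in the units of
#'     the coarse-grained series (seconds squared for RR variance).}
#'   \item{`percent_of_reference_series`}{`r` is a percentage of the SD of
#'     a caller-designated reference series (typically one of the first
#'     variance coarse-grained series); pass that series to [resolve_r()].}
#' }
#'
#' @param m template length, positive integer (default 2).
#' @param r_mode tolerance convention, see Details.
#' @param r_value percentage for the percent modes, or the absolute
#'   tolerance for `fixed_absolute`.
#' @param resolved_r absolute tolerance, filled by [resolve_r()]; may be
#'   supplied directly.
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L,
                           r_mode = c("percent_of_sd", "fixed_absolute",
                                      "percent_of_reference_series"),
                           r_value = 0.5, resolved_r = NA_real_) {
  r_mode <- match.arg(r_mode)
  if (!is_count(m, min = 1L)) stop_validation("m must be a positive integer")
  if (!is.numeric(r_value) || length(r_value) != 1L || !is.finite(r_value) ||
      r_value <= 0) {
    stop_validation("r_value must be a positive number")
  }
  if (!is.na(resolved_r) && resolved_r <= 0) {
    stop_validation("resolved_r must be positive")
  }
  structure(list(m = as.integer(m), r_mode = r_mode,
                 r_value = as.numeric(r_value),
                 resolved_r = as.numeric(resolved_r)),
            class = "entropy_params")
}

#' Resolve the absolute tolerance r from a reference series
#'
#' For the percent modes, `resolved_r` becomes `r_value / 100` times the
#' sample standard deviation of `reference`: the original (filtered) series
#' for `percent_of_sd`, or a designated coarse-grained series for
#' `percent_of_reference_series`. For `fixed_absolute`, `resolved_r` is
#' simply `r_value`. The resolved tolerance is then held constant across
#' all scales of a multiscale analysis.
#'
#' @param reference numeric vector or [rr_series()] (ignored for
#'   `fixed_absolute`).
#' @param params an [entropy_params()] object.
#' @return `params` with `resolved_r` filled in.
#' @export
resolve_r <- function(reference, params) {
  if (!inherits(params, "entropy_params")) stop_validation("params must be entropy_params")
  if (params$r_mode == "fixed_absolute") {
    params$resolved_r <- params$r_value
    return(params)
  }
  ref <- series_values(reference)
  if (length(ref) < 2L) stop_validation("reference series too short to take an SD")
  s <- stats::sd(ref)
  if (!is.finite(s) || s <= 0) stop_validation("tolerance resolves to zero: reference series has zero variance")
  params$resolved_r <- params$r_value / 100 * s
  params
}

#' Sample entropy of a numeric series
#'
#' SampEn(m, r) = -ln(A / B), where B counts unordered pairs of distinct
#' length-`m` templates of consecutive points matching within tolerance `r`
#' (Chebyshev distance, strictly `< r`, self-matches excluded) and A counts
#' those same pairs whose length-(`m + 1`) extensions also match. Both
#' counts run over the same template start set (the first `N - m`
#' positions), so every template considered has an extension.
#'
#' When no template pairs match at length `m` (`B = 0`) or none of the
#' matching pairs extend (`A = 0`), the entropy is undefined: the estimate
#' is returned with `value = NA` and `defined = FALSE` rather than raising
#' an error, since long scales on short series can legitimately yield no
#' matches. Downstream consumers ([complexity_index()]) decide how to
#' treat undefined scales.
#'
#' @param x numeric vector (or [rr_series()]), length at least `m + 2`,
#'   all values finite.
#' @param m template length, positive integer.
#' @param r absolute tolerance, `> 0`, in the units of `x`.
#' @return An object of class `entropy_estimate` with fields `value`
#'   (nats, `NA` if undefined), `m`, `r`, `n`, `n_templates`, `matches_m`
#'   (B), `matches_m1` (A), `defined`, `statistic`.
#' @examples
#' sample_entropy(rep(c(0.5, 1), 25), m = 2, r = 0.3)$value  # 0: periodic
#' @export
sample_entropy <- function(x, m = 2L, r) {
  x <- series_values(x)
  if (!is_count(m, min = 1L)) stop_validation("m must be a positive integer")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop_validation("tolerance r must be a positive number")
  }
  n <- length(x)
  if (n < m + 2L) {
    stop_validation("series too short for sample entropy: need >= %d points for m = %d, got %d",
                    m + 2L, m, n)
  }
  if (!all(is.finite(x))) stop_validation("series contains non-finite values")
  counts <- .sampen_counts(as.numeric(x), as.integer(m), as.numeric(r))
  A <- counts[["A"]]; B <- counts[["B"]]
  defined <- A > 0 && B > 0
  structure(list(value = if (defined) -log(A / B) else NA_real_,
                 m = as.integer(m), r = as.numeric(r), n = n,
                 n_templates = n - m, matches_m = B, matches_m1 = A,
                 defined = defined, statistic = "sampen"),
            class = "entropy_estimate")
}

#' Quadratic sample entropy
#'
#' QSE(m, r) = SampEn(m, r) + ln(2 r), a tolerance-normalised entropy (the
#' match probability is converted to a density estimate over the tolerance
#' band of width 2r) that mitigates the dependence of sample entropy on the
#' choice of r and the influence of outliers on the SD-based tolerance.
#' Undefined whenever the underlying sample entropy is undefined.
#'
#' @inheritParams sample_entropy
#' @return An `entropy_estimate` with `statistic = "qse"`.
#' @export
quadratic_sample_entropy <- function(x, m = 2L, r) {
  est <- sample_entropy(x, m = m, r = r)
  est$value <- est$value + log(2 * r)
  est$statistic <- "qse"
  est
}

#' @export
print.entropy_estimate <- function(x, ...) {
  lbl <- c(sampen = "SampEn", qse = "QSE")[[x$statistic]]
  if (x$defined) {
    cat(sprintf("%s(m = %d, r = %.6g) = %.4f nats  [n = %d, B = %.0f, A = %.0f]\n",
                lbl, x$m, x$r, x$value, x$n, x$matches_m, x$matches_m1))
  } else {
    cat(sprintf("%s(m = %d, r = %.6g) undefined: no template matches (B = %.0f, A = %.0f)\n",
                lbl, x$m, x$r, x$matches_m, x$matches_m1))
  }
  invisible(x)
}
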