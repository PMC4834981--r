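#' Synthetic reference signals and RR-like series
#'
#' Deterministic (seeded) generators for the reference processes used to
#' characterise and test multiscale entropy estimators, plus an
#' RR-interval-like generator with labeled ectopic beats for exercising
#' the artifact filter. The same seed always reproduces the same output
#' bit for bit; no generator touches the global random stream.
#'
#' `synth_signal()` is a single dispatching front end over the individual
#' generators; the `...` are passed through to the chosen generator.
#'
#' @param kind one of `"white_gaussian"`, `"one_over_f"`, `"periodic"`,
#'   `"ar1"`, `"rr_like"`.
#' @param n series length, at least 2.
#' @param seed integer RNG seed.
#' @param ... generator-specific parameters.
#' @return Numeric vector of length `n` for the signal generators; for
#'   `"rr_like"` see [synth_rr_like()].
#' @export
synth_signal <- function(kind = c("white_gaussian", "one_over_f", "periodic",
                                  "ar1", "rr_like"),
                         n, seed = 1L, ...) {
  kind <- match.arg(kind)
  switch(kind,
    white_gaussian = synth_white(n, seed = seed, ...),
    one_over_f = synth_one_over_f(n, seed = seed, ...),
    periodic = synth_periodic(n, ...),
    ar1 = synth_ar1(n, seed = seed, ...),
    rr_like = synth_rr_like(n, seed = seed, ...))
}

check_n <- function(n) {
  if (!is_count(n, min = 2L)) stop_validation("n must be an integer >= 2")
  as.integer(n)
}

#' @rdname synth_signal
#' @param mean,sd mean and standard deviation of the Gaussian marginals.
#' @export
synth_white <- function(n, sd = 1, mean = 0, seed = 1L) {
  n <- check_n(n)
  if (sd <= 0) stop_validation("sd must be positive")
  with_seed(seed, stats::rnorm(n, mean = mean, sd = sd))
}

#' 1/f (colored) noise by spectral synthesis
#'
#' Frequency-domain synthesis: Fourier amplitudes proportional to
#' `f^(-beta/2)` (so the power spectrum decays as `f^-beta`), phases
#' i.i.d. uniform, zero-frequency component set to 0, inverse transform,
#' then rescaled to the requested standard deviation. `beta = 1` gives
#' classic 1/f noise with long-range correlations; `beta = 0` is white.
#'
#' @inheritParams synth_white
#' @param beta spectral exponent, in `[0, 2]`.
#' @export
synth_one_over_f <- function(n, beta = 1, sd = 1, seed = 1L) {
  n <- check_n(n)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 2) {
    stop_validation("beta must lie in [0, 2]")
  }
  if (sd <= 0) stop_validation("sd must be positive")
  with_seed(seed, {
    nhalf <- n %/% 2L
    f <- seq_len(nhalf) / n                       # positive frequencies
    amp <- f^(-beta / 2)
    phase <- stats::runif(nhalf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phase)
    if (n %% 2L == 0L) spec[nhalf] <- complex(real = amp[nhalf], imaginary = 0)
    full <- c(complex(real = 0),                  # zero mean
              spec,
              Conj(rev(spec[seq_len(nhalf - (1L - n %% 2L))])))
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    x / stats::sd(x) * sd
  })
}

#' @rdname synth_signal
#' @param period period of the sinusoid, in samples.
#' @param amplitude peak amplitude of the sinusoid.
#' @export
synth_periodic <- function(n, period = 40, amplitude = 1, ...) {
  n <- check_n(n)
  if (period <= 0 || amplitude <= 0) {
    stop_validation("period and amplitude must be positive")
  }
  amplitude * sin(2 * pi * (seq_len(n) - 1L) / period)
}

#' @rdname synth_signal
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @export
synth_ar1 <- function(n, phi = 0.9, sd = 1, seed = 1L) {
  n <- check_n(n)
  if (!is.numeric(phi) || length(phi) != 1L || abs(phi) >= 1) {
    stop_validation("AR coefficient phi must satisfy |phi| < 1")
  }
  if (sd <= 0) stop_validation("sd must be positive")
  with_seed(seed, {
    e <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
    x <- numeric(n)
    x[1L] <- stats::rnorm(1L, sd = sd)           # stationary start
    for (i in seq_len(n - 1L)) x[i + 1L] <- phi * x[i] + e[i + 1L]
    x
  })
}

#' RR-interval-like series with labeled ectopic beats
#'
#' Emulates the gross features of a Holter-derived RR series: a positive
#' baseline interval, a slow sinusoidal trend (autonomic/circadian-like
#' modulation), Gaussian beat-to-beat noise, and ectopic events injected
#' at a given rate. Each ectopic event mimics a premature beat with a
#' compensatory pause: a randomly chosen interval is shortened to 0.5x its
#' value and the following interval lengthened to 1.5x. The indices of
#' the perturbed intervals (both members of each pair) are returned as
#' ground-truth labels, so filter sensitivity and specificity can be
#' measured against them.
#'
#' @inheritParams synth_white
#' @param baseline mean interval, seconds (default 0.8 s, i.e. 75 bpm).
#' @param trend_amplitude amplitude of the slow trend, seconds.
#' @param trend_period period of the slow trend, in beats.
#' @param noise_sd SD of beat-to-beat Gaussian noise, seconds.
#' @param ectopy_rate fraction of beats at which an ectopic pair is
#'   injected, in `[0, 0.2]`.
#' @return A list of class `rr_like_synth`: `series` (an [rr_series()]),
#'   `ectopic_idx` (integer indices of the perturbed intervals).
#' @export
synth_rr_like <- function(n, seed = 1L, baseline = 0.8,
                          trend_amplitude = 0.05, trend_period = 1000,
                          noise_sd = 0.03, ectopy_rate = 0.01) {
  n <- check_n(n)
  if (baseline <= 0 || noise_sd < 0 || trend_amplitude < 0) {
    stop_validation("baseline must be positive; amplitudes non-negative")
  }
  if (ectopy_rate < 0 || ectopy_rate > 0.2) {
    stop_validation("ectopy_rate must lie in [0, 0.2]")
  }
  with_seed(seed, {
    x <- baseline +
      trend_amplitude * sin(2 * pi * (seq_len(n) - 1L) / trend_period) +
      stats::rnorm(n, sd = noise_sd)
    x <- pmax(x, 0.25)                    # physiologic floor, ~240 bpm
    n_event <- round(ectopy_rate * n)
    ect <- integer(0)
    if (n_event > 0L) {
      # event sites >= 3 apart so (short, long) pairs never overlap
      cand <- sample.int(n - 1L, min(n - 1L, 4L * n_event))
      sites <- integer(0)
      for (s in cand) {
        if (length(sites) == n_event) break
        if (all(abs(s - sites) >= 3L)) sites <- c(sites, s)
      }
      for (s in sort(sites)) {
        x[s + 1L] <- 1.5 * x[s]
        x[s] <- 0.5 * x[s]
      }
      ect <- sort(as.vector(rbind(sites, sites + 1L)))
    }
    structure(list(series = rr_series(x, label = sprintf("rr_like(seed=%d)", seed)),
                   ectopic_idx = ect),
              class = "rr_like_synth")
  })
}

#' RR-like series with a prescribed volatility structure
#'
#' Generates `x_t = baseline + s_t * eps_t` with i.i.d. standard Gaussian
#' `eps_t` and a log-normal local volatility `s_t = base_sd * exp(kappa *
#' v_t)`, where the driver `v_t` (standardised to zero mean, unit SD) is
#' 1/f noise, a stationary AR(1), or i.i.d. Gaussian noise. The three
#' drivers give volatility series of decreasing temporal structure at the
#' segment scales probed by variance coarse-graining: 1/f modulation
#' fluctuates at every scale; AR(1) modulation (default `phi = 0.7`,
#' memory of a few beats, respiratory-cycle order) survives only at short
#' scales; per-beat i.i.d. modulation averages out within segments,
#' leaving no coarse-scale volatility structure at all. Cohorts built from
#' them therefore have a known ordering of multiscale volatility
#' complexity, used for the cohort-level ordering checks.
#'
#' @inheritParams synth_white
#' @param driver `"one_over_f"`, `"ar1"` or `"iid"` volatility modulation.
#' @param baseline mean interval, seconds.
#' @param base_sd median local SD of the series, seconds.
#' @param kappa log-volatility modulation depth (dimensionless).
#' @param beta spectral exponent of the 1/f driver.
#' @param phi AR(1) coefficient of the AR driver.
#' @return An [rr_series()].
#' @export
synth_volatility_rr <- function(n, driver = c("one_over_f", "ar1", "iid"),
                                seed = 1L, baseline = 0.8, base_sd = 0.04,
                                kappa = 0.2, beta = 1, phi = 0.7) {
  driver <- match.arg(driver)
  n <- check_n(n)
  v <- switch(driver,
    one_over_f = synth_one_over_f(n, beta = beta, sd = 1, seed = seed),
    ar1 = synth_ar1(n, phi = phi, sd = 1, seed = seed),
    iid = synth_white(n, sd = 1, seed = seed))
  v <- (v - mean(v)) / stats::sd(v)
  eps <- with_seed(seed + 1000003L, stats::rnorm(n))
  x <- baseline + base_sd * exp(kappa * v) * eps
  rr_series(pmax(x, 0.25),
            label = sprintf("vol_%s(seed=%d)", driver, seed))
}
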