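---
title: "Generalized multiscale entropy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized multiscale entropy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmse)
```

## The method

Multiscale entropy analysis quantifies the complexity of a time series by
estimating its unpredictability at many levels of temporal resolution.
Given a series $\{x_i\}$, $1 \le i \le N$, the procedure at scale factor
$\tau$ is:

1. divide the series into non-overlapping segments of $\tau$ consecutive
   points (left-aligned; a trailing remainder shorter than $\tau$ is
   discarded);
2. summarise each segment with a statistical moment, producing the
   coarse-grained series at scale $\tau$;
3. estimate the sample entropy of the coarse-grained series;
4. sum the entropies over an inclusive range of scales into a single
   *complexity index*.

The classical form of the method uses the segment **mean** (we write
$\mathrm{MSE}_\mu$). This package generalises the coarse-graining moment:
with the unbiased segment **variance**,
$\hat\sigma^2 = \frac{1}{\tau-1}\sum_{i=1}^{\tau}(x_i-\bar x)^2$,
the coarse-grained series at scale $\tau$ is the signal's *volatility*
observed at that resolution, and the resulting curve
($\mathrm{MSE}_{\sigma^2}$) measures the multiscale temporal structure of
the volatility rather than of the local mean. A skewness hook is included
as a third-moment extension point; it is implemented and tested but not
used by any shipped analysis. For cardiac interbeat (RR) series the
volatility index degrades with aging and congestive heart failure, which
is the motivating application; the package itself is signal-agnostic.

A complexity index defined as a sum over scales is deliberately different
from single-scale irregularity: uncorrelated noise is maximally irregular
at scale 1 but carries no structure across scales, while signals with
$1/f$-type long-range correlations sustain entropy over a wide range of
scales and therefore accumulate a larger index. Periodic signals score
low everywhere.

## Sample entropy conventions

For template length $m$ and tolerance $r$,
$\mathrm{SampEn} = -\ln(A/B)$, where $B$ counts unordered pairs of
distinct length-$m$ templates of consecutive points whose Chebyshev
distance is strictly less than $r$, and $A$ counts those same pairs whose
length-$(m+1)$ extensions also match. Conventions that change counts at
the margins, made explicit because they matter for exact reproducibility:

* both counts run over the same template start set, the first $N-m$
  positions, so every template considered has an extension;
* self-matches are excluded; pairs are unordered;
* the match criterion is strict (`< r`); at exact ties `<=` would give
  different counts;
* when $B = 0$ or $A = 0$ the entropy is *undefined* and returned as a
  flagged `NA`, never an exception — long scales on short series can
  legitimately produce no matches, and the downstream index must decide
  (policy `strict` refuses to sum such a curve; `skip_undefined` sums the
  defined scales and reports the rest).

The kernel sorts template start indices by their first coordinate and
walks a two-pointer window, so only pairs whose first coordinates differ
by less than $r$ are ever compared in full. This is exact — the unit and
acceptance suites verify count-for-count agreement with an $O(N^2)$
double loop — and fast enough for $N = 10^5$ series in a couple of
seconds. Counts are accumulated in 64-bit integers.

Quadratic sample entropy, $\mathrm{QSE} = \mathrm{SampEn} + \ln(2r)$,
converts the match probability into a density over the tolerance band;
it reduces the sensitivity of group comparisons to the choice of $r$ and
to outlier-inflated SDs, and is provided as a drop-in alternative.

### Tolerance resolution

`r` is resolved **once**, from the original (post-filter) series, and
held constant across all scales: `percent_of_sd` with `r_value = 15` (of
the SD, in percent) is the standard configuration for mean
coarse-graining, and `r_value = 0.5` for variance coarse-graining —
variance coarse-grained amplitudes are far smaller than mean
coarse-grained ones, so the tolerance must shrink accordingly. Two
alternatives are provided because they change the estimator's robustness
trade-offs: a `fixed_absolute` tolerance (e.g. $2\times10^{-4}\,s^2$ for
RR variance series), and `percent_of_reference_series`, which takes the
SD of a caller-designated reference (typically one of the first variance
coarse-grained series). A non-default `r_per_scale` switch re-resolves
the percentage at every scale; it is a different statistic and is never
used implicitly.

## The RR artifact filter

Ectopic beats and detection artifacts produce spurious short/long RR
intervals that inflate segment variances. The filter excludes the
central point of a moving window of length $l$ when it lies outside
$[\,(1-a)\bar x_i,\ (1+a)\bar x_i\,]$, where $\bar x_i$ is the window
mean computed *excluding* the central point. Defaults $l = 41$,
$a = 0.2$ are the values conventionally used for 24-h Holter series.
Decisions the underlying definition leaves open, fixed here explicitly:

* decisions are made against the original series in a single pass and
  excluded points are removed afterwards (deterministic and
  order-independent); an `iterate` option repeats passes until stable,
  which catches beats masked by a neighbouring artifact's contribution
  to their window mean;
* edge points without a full centered window are evaluated against a
  truncated window requiring at least $(l-1)/2$ neighbours
  (`edges = "truncated"`), or never excluded (`edges = "keep"`);
* excluded beats are removed and the survivors concatenated — no
  interpolation, matching standard practice for entropy analysis;
* report indices are 1-based, the native R convention.

The criterion is relative, so the excluded set is invariant under
rescaling of the series (tested).

## Synthetic data: what it emulates, and what it does not

All generators are seeded and bit-reproducible, and none touches the
global RNG stream.

* `synth_white`, `synth_ar1`, `synth_periodic` — textbook reference
  processes.
* `synth_one_over_f` — spectral synthesis: Fourier amplitudes
  $\propto f^{-\beta/2}$, i.i.d. uniform phases, zero DC, inverse
  transform, rescaled to the target SD. The target spectrum is exact by
  construction, which makes the periodogram-slope check a sharp oracle.
* `synth_rr_like` — baseline 0.8 s + slow sinusoidal trend (amplitude
  0.05 s, period 1000 beats) + Gaussian beat-to-beat noise (SD 0.03 s),
  with ectopic events at a configurable rate modelled as a premature
  beat with compensatory pause: an interval shortened to $0.5\times$
  followed by one lengthened to $1.5\times$. Both members of each pair
  are returned as ground-truth labels, so filter sensitivity (fraction
  of injected intervals excluded) and clean-beat exclusion rate are
  measurable exactly.
* `synth_volatility_rr` — $x_t = 0.8 + s_t\,\varepsilon_t$ with
  log-normal local volatility $s_t = 0.04\,e^{\kappa v_t}$ and a choice
  of standardized volatility driver $v_t$.

The volatility drivers define the three-group cohort used for ordering
checks, and their parameters were fixed once, at design time, on
physiologic grounds. Variance coarse-graining probes volatility
structure *at segment scales* (10–100 beats here). Per-beat i.i.d.
modulation averages out within every segment, so it contributes no
coarse-scale volatility structure at all — it is the least-structured
construction by design, not merely empirically. An AR(1) driver with
$\phi = 0.7$ has a memory of a few beats (respiratory-cycle order):
shorter than every analysis segment, but enough to survive partial
averaging at the short end of the scale range. The $1/f$ driver
($\beta = 1$) fluctuates at every scale, emulating multiscale autonomic
modulation. The intended complexity ordering
$1/f > \mathrm{AR}(1) > \mathrm{iid}$ is therefore a property of the
construction; the cohort tests check that the pipeline recovers it. The
modulation depth $\kappa = 0.2$ (local SD varying by roughly $\pm 50\%$
over $\pm 2$ driver SDs) is of the order seen in healthy heart rate
variability. Note that the AR memory must sit strictly between one beat
and the shortest segment: a driver with memory comparable to the largest
segments would retain "fresh" volatility at every analysis scale and is
not intermediate in this construction.

What the synthetic cohort does **not** emulate: real RR nonstationarity
(activity, circadian load), measurement noise correlated with heart
rate, the heavy-tailed artifact mixture of real Holter exports, or
sampling-frequency quantisation. Passing the synthetic checks
demonstrates the estimator chain is correct and sensitive to
segment-scale volatility structure; it does not by itself demonstrate
clinical validity on real recordings. Reproducing the published three-group
24-h Holter analysis requires the PhysioNet nsrdb/nsr2db/chfdb/chf2db
recordings, which cannot be shipped with the package; the corresponding
acceptance test documents the expected layout
(`tests/testthat/physionet/{young,older,chf}/`) and reports a failure,
not a silent skip, when the data are absent.

## Numerical choices

* Segment variance uses the two-pass (centered) formula; the one-pass
  $E[x^2]-E[x]^2$ form loses digits exactly in the RR regime (values
  ~0.8 s, variances ~$10^{-4}\,s^2$). The rolling display helper *does*
  use running sums, after centering the whole series once, which is
  adequate for display.
* Curve files are written with 17 significant digits so write → read is
  bit-exact; RR files default to 15 digits, which round-trips any value
  that itself came from a ≤15-digit text file.
* The white-noise monotonicity and 1/f-flatness properties of
  $\mathrm{MSE}_\mu$ are asserted on curves averaged over 10 seeds;
  per-seed curves at $n = 2^{14}$ carry visible sampling noise.
* Problem sizes in the test and acceptance suites — $N = 10^5$ for the
  Gaussian closed-form check, $n = 2^{14}$ for reference-signal curves,
  $10^4$-point series and 20 subjects per group for the cohort study —
  were chosen as the smallest sizes at which the Monte-Carlo error bands
  quoted with each check are comfortably respected.
* Seeds for internally derived streams (e.g. the volatility generator's
  independent $\varepsilon_t$ stream) are offset by fixed large
  constants from the user seed, keeping every stream reproducible and
  distinct while staying within 32-bit integer range.

## Known limitations

* Entropy estimates at scales where fewer than ~100 coarse-grained
  points remain are noisy; `mse_curve()` warns (once per call) but does
  not refuse. For the standard scale range 10–100 this means series of
  at least $10^4$ beats are advisable.
* No refined-composite or short-series multiscale entropy variants are
  provided; the coarse-graining here is the plain non-overlapping form.
* The Mann-Whitney comparison is the only inferential procedure shipped;
  it is deliberately thin plumbing around `stats::wilcox.test()` (exact
  for tie-free groups of ≤ 20, midranks + normal approximation with tie
  and continuity correction otherwise).
* The filter is a pure exclusion filter: no imputation, and excluded
  beats simply shift later beats forward before segmentation, as is
  standard for entropy analysis of RR series.
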