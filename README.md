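# gmse — generalized multiscale entropy analysis

`gmse` quantifies the multiscale complexity of physiologic time series,
with heart rate variability as the primary use case. It is written for
researchers who work with cardiac interbeat (RR) interval recordings —
typically 24-h Holter exports — and want a reproducible pipeline from raw
interval lists to per-subject complexity indices and cohort-level group
comparisons, either from R or from the shell.

## The method

Classical multiscale entropy coarse-grains a series
{x<sub>i</sub>}, 1 ≤ i ≤ N, by replacing non-overlapping segments of
length τ with their **mean**, then estimates the sample entropy

&nbsp;&nbsp;&nbsp;&nbsp;SampEn(m, r) = −ln(A/B)

of each coarse-grained series (B = pairs of length-m templates within
Chebyshev tolerance r; A = those pairs still matching at length m+1),
and sums the entropies over a range of scales into a **complexity
index**. `gmse` generalises the coarse-graining statistic to a family of
moments: the mean (MSE<sub>μ</sub>), the unbiased segment variance
(MSE<sub>σ²</sub>, denominator τ−1), and a skewness extension hook.
The variance member measures the multiscale temporal structure of a
signal's *volatility*; in heartbeat series this volatility complexity is
high in health and degrades with aging and congestive heart failure.

The package provides:

* `read_rr()` / `write_rr()` / `write_curve()` / `write_index_json()` —
  plain-text I/O for RR series, entropy curves and index summaries;
* `filter_rr()` — the moving-window artifact filter for ectopic beats
  and detection errors (default window l = 41 beats, relative tolerance
  a = 0.2);
* `coarse_grain()`, `rolling_moment()` — moment coarse-graining and a
  moving-window display helper;
* `sample_entropy()`, `quadratic_sample_entropy()`, `resolve_r()` —
  entropy estimation with the field's tolerance conventions (r as a
  percentage of the original series' SD, a fixed absolute value, or a
  percentage of a designated reference series);
* `mse_curve()`, `complexity_index()` — the multiscale orchestration;
* `synth_*()` — seeded generators for white/1-over-f/periodic/AR(1)
  signals, RR-like series with labeled ectopy, and volatility-structured
  RR cohorts;
* `run_cohort()`, `compare_groups()` — batch analysis with two-sided
  Mann-Whitney group comparison;
* a `gmse` command-line tool (`exec/gmse`) with `filter`, `coarsegrain`,
  `entropy`, `msen`, `synth` and `cohort` subcommands.

## Worked example

Analyse a synthetic 20 000-beat RR-like recording with 1% injected
ectopy, exactly as one would a real Holter export:

```r
library(gmse)

s  <- synth_rr_like(20000, seed = 42, ectopy_rate = 0.01)
rr <- filter_rr(s$series, filter_params(l = 41, a = 0.2))
rr
#> RR series 'rr_like(seed=42)': 19600 intervals, mean 0.7999 s, SD 0.0467 s
#>   filtered: 400 of 20000 input beats excluded

curve <- mse_curve(rr, moment = "variance", scales = 10:100,
                   params = entropy_params(m = 2, r_mode = "percent_of_sd",
                                           r_value = 0.5))
curve
#> MSE curve (moment = variance) for 'rr_like(seed=42)': scales 10-100, m = 2, r = 0.000233546
#>   91/91 scales defined; entropy range [0.213, 1.136] nats

complexity_index(curve, 10, 100, policy = "strict")
#> complexity index ('rr_like(seed=42)', scales 10-100): 44.861 nats over 91 defined scales
```

The filter removed exactly the 400 injected ectopic intervals (200
premature-beat/compensatory-pause pairs) and nothing else. The tolerance
r resolved to 0.5% of the filtered series' SD (0.000234 s) and was held
fixed across all 91 scales. The index, 44.9 nats, is the sum of the 91
per-scale entropies; a series with genuine multiscale volatility
structure scores higher under the same settings:

```r
vol <- synth_volatility_rr(20000, driver = "one_over_f", seed = 42)
complexity_index(mse_curve(vol, moment = "variance", scales = 10:100,
                           params = entropy_params(m = 2, r_value = 0.5)))
#> complexity index ('vol_one_over_f(seed=42)', scales 10-100): 129.283 nats over 91 defined scales
```

The same pipeline from the shell:

```sh
gmse filter --l 41 --a 0.2 subject.txt subject.filt.txt
gmse msen --moment variance --scales 10:100 --m 2 \
     --r-mode percent_of_sd --r 0.5 --policy strict subject.filt.txt
```

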