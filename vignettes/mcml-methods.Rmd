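---
title: "Maximum-correlation analog forecasting and time-lagged diagnostics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-correlation analog forecasting and time-lagged diagnostics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcml)
```

This vignette is the package's own account of the science it implements:
the forecasting model and its assumptions, the tunable parameters, what the
synthetic generators do and do not emulate, and the numerical and design
choices made where the method leaves room.

## The working scale

All forecasting happens on `Y = log(Z + offset)` with `offset = 0.05`. The
log compresses the wide dynamic range of epidemic case rates (troughs near
zero, peaks in the hundreds per million); the offset keeps the transform
defined at zero while remaining small against typical case rates. The
offset is exposed everywhere (`log_transform()`, `mcml_run()`) because
series on other scales (index points, population counts) may warrant a
different choice. Forecast errors are reported on this log scale — the
scale on which the method operates — with a back-transformed set
(`metrics_raw`) alongside.

The method's premise is that such series are *not* Markov: the history
beyond yesterday carries predictive information, expressed through lagged
values of `Y`.

## Stage 1: principal lags by BIC

For each candidate lag count `p` in `2..q` we regress the one-day change
`D_i = Y_i − Y_{i−1}` on `(Y_{i−2}, …, Y_{i−p−1})` with an intercept and
score the fit with `BIC(p) = m log(rss/m) + (p + 2) log(m)`. The parameter
count includes the intercept, the `p` slopes and the error variance; the
`+1` for the variance is shared by all candidates and cannot change the
argmin, but it pins the formula down exactly.

Two choices deserve comment:

* **Common response rows.** The textbook row range for a `p`-lag model
  starts at `i = p + 2`, which would make models with different `p` explain
  *different* response vectors; BIC differences across different data are
  not meaningful. By default every candidate is therefore fitted to the
  identical `m` most recent eligible rows (`rows = "aligned"`). The
  start-anchored ranges remain available as `rows = "literal"` for
  compatibility.
* **Defaults `q = 19`, `m = min(60, floor(n/4))`.** Nineteen lags cover
  almost three weeks of daily history — beyond the generation interval of
  the epidemic application — while `m` respects the small-sample regime the
  method was designed for (`m < n/4`, with 60 rows the demonstrated
  working size).

Ties in the BIC curve break toward smaller `p` (parsimony), and a
numerically perfect fit (relative `rss` below `1e-12` of the response
energy) is assigned `BIC = −∞`, so exact linear structure wins selection
deterministically; among several perfect fits the smallest `p` wins by the
same tie rule. Degenerate designs (constant or duplicated lag columns) are
skipped; selection fails only if every candidate is degenerate.

## Stage 2: maximum-correlation analog matching

The forecast of the next change is an *analog*: among all historical
anchors `i`, find the principal-lag window most Pearson-correlated with
the current one and reuse the change `D_{i*}` that followed it. Multi-step
forecasts iterate this, composing the query from predicted values as the
horizon advances, while the candidate library stays frozen to training
anchors — predicted values are never matched against, which prevents
feedback contamination.

Numerical conventions:

* Zero-variance candidate windows have undefined correlation; they are
  skipped and counted (`n_skipped`), not scored 0.
* A zero-variance *query* aborts a single-step search; inside a multi-step
  run it falls back to a zero increment with a warning, so a long flat
  stretch degrades gracefully instead of failing the run.
* Exact correlation ties break toward the most recent anchor, on the view
  that recent dynamics are the more relevant analog. This makes the
  forecast deterministic and testable (periodic series must match exactly
  one period back).
* The split `N = round(train_frac · n)` is strictly chronological. The
  test block is touched only by the final metric computation.

Because Pearson correlation is affine-invariant, rescaling the raw series
(positive slope) leaves all matched anchors unchanged — a property the
test suite checks both at the window level and through the full pipeline.

MAPE uses a `1e-8` zero guard on the truth values; excluded points are
counted and reported rather than silently dropped. `MAE ≤ RMSE` holds by
Jensen's inequality and is asserted as a property test.

## Time-lagged diagnostics

`sliding_features()` uses *trailing* windows (default 150 days at lag 15),
so every value is computable in real time on the day it is dated — the
point of a day-by-day early-warning diagnostic. Whether a centered window
would reproduce published retrospective figures better is knowingly left
aside; causality wins here.

The windowed autocorrelation estimator divides a truncated lagged
covariance by the full-window variance, so its extreme value at a
half-period lag is `−(window − lag)/window` (−0.9 at the defaults), not
−1; tests assert the estimator's own closed form.

**AMI.** The average mutual information uses an equal-width histogram
estimator with 16 bins over the range of the *whole* series, both pair
members binned with the same edges; values are in nats. Neither the bin
count nor the log base is canonical in the chaos literature, so both are
explicit parameters; 16 equal-width bins is the common toolkit default.
Binning the two pair members identically makes `AMI(0)` equal the binned
marginal entropy exactly, which the tests exploit (`log 2` on a balanced
two-level series). The `[0, 1]` normalization by mean marginal entropy is
implemented but off by default. The estimator's finite-sample bias on
independent data is roughly `(bins − 1)²/(2 · pairs)` nats (≈ 0.011 at
10,000 points), well inside the 0.05 independence bound the acceptance
suite checks.

**Dynamic scaling.** `(ac + 1)` and `ami` are multiplied by half the
window maximum of new cases, bringing all three axes to comparable ranges
day by day; the alternative of dividing new cases by their window maximum
is available (`normalize_nc = TRUE`) but compresses upswings, since during
growth every day sets a new window maximum. Per-axis constants
(`arbitrary_scale()`) are accepted via configuration only — no automatic
selection rule is offered, because there is no principled one; the factors
are recorded in the output's metadata for audit.

**Local Lyapunov exponents.** `λ_t = log(gap_{t+1}/gap_t)` for each of the
three axis pairs; the MLE is the per-day maximum over defined pairs. Zero
gaps are masked (`NA`) rather than scored `±∞`, and a day on which all
three pairs are masked yields a masked MLE. Each λ describes the
transition from day `t` to `t + 1` and is dated by the *later* day — the
day on which the expansion is first observable.

**Peak/spike alignment.** Peak detection uses topographic prominence (≥
10% of the series range) and a 14-day separation, with matching within ±21
days; none of these numbers is canonical, so all are parameters. The
pairing rule deserves a note: the scientific question is whether a warning
was available *at or before* a case peak, so the default
(`prefer = "lead"`) pairs each case peak with the nearest MLE spike at
non-negative lead when one exists in the window, falling back to the
nearest trailing spike. The plain nearest-spike rule
(`prefer = "nearest"`) is kept for symmetric analyses. On smooth synthetic
waves the dominant spikes arise where the falling case curve re-crosses
the scaled AC/AMI trajectories — a few days *after* the peak — while
secondary upswing crossings provide the pre-peak spikes; a symmetric
nearest rule systematically reports the trailing spike even when an
earlier warning existed, which is the wrong summary of an early-warning
diagnostic.

## Synthetic generators: what they emulate

All generators are pure functions of their configuration, seed included
(bit-identical reruns), built on R's seeded generator via `withr`.

* `gen_epidemic_waves()`: Gaussian pulses plus multiplicative log-normal
  noise (`sdlog = 0.05`), clipped at zero. The presets place waves roughly
  six months apart with peak rates of 120–400 per million and widths of
  25–35 days — the scale of major COVID-19 waves in per-million smoothed
  data. What they do **not** emulate: weekday reporting artifacts,
  asymmetric rise/decay, variant-driven shape changes, or the strong
  serial correlation that 7-day averaging induces in real noise. Passing
  tests on these fixtures show the machinery is correct, not that real
  surveillance data will be forecast with any particular accuracy.
* `gen_lagged_linear()`: builds `Y` so its differences follow a known
  3-lag linear model. The default coefficients `(0, 0.729, −0.729)` come
  from placing the characteristic roots of the level recursion at
  `{1, 0.9, 0.9 e^{±2πi/3}}`: the unit root is inherent to modelling
  *differences* (levels integrate), and the damped three-day oscillation
  makes all configured lags genuinely informative while keeping the
  differences stationary. Coefficient sets with spectral radius beyond 1
  make the levels explode within a few hundred steps and trigger a
  stability warning. Because the process is linear in its innovations, the
  BIC recovery rate is invariant to `σ`; the residual ~8% failure rate at
  `m = 60` is BIC's own overfitting probability (≈
  `P(χ²_k > k log 60)` summed over larger models), not a generator
  property.
* `gen_periodic()`: one cycle built once and tiled, so periodicity holds
  bit-exactly — the fixture behind the exact-recall property (a noiseless
  periodic series whose period fits twice in training must be forecast
  with zero error).
* `gen_logistic_map()`: two trajectories of the chaotic `r = 4` logistic
  map separated by `1e-9`. Over the first 20 steps the gap stays in the
  linearizable regime, so the mean local exponent estimates the map's
  known Lyapunov exponent `log 2`.
* `gen_blowfly_like()`: a Ricker-type recursion with delayed density
  dependence (`a = 2`, `d = 9`, `K = 1000`), giving the sustained
  quasi-cycles of laboratory blowfly populations.
* `gen_white_noise()`: the negative control — flat AMI profile, no
  informative lags.

## Problem sizes

The test and acceptance runs use the sizes the fixtures were designed
around: series of 280–840 days, lag selection at `n = 400`, `m = 60`,
`q = 19` over 100 seeds, analog-search oracle checks on 50 series of
length 120, AMI bounds at 10,000 points over 20 seeds. These keep the full
suite in the tens of seconds while leaving every estimator in its intended
sample-size regime.

## Known limitations

* The analog forecaster assumes the future rhymes with the training set;
  it cannot extrapolate dynamics it has never seen (a first wave taller
  than anything in training is predicted from the closest smaller analog),
  and its quality degrades on very noisy series.
* Metrics on the log scale understate errors near zero incidence on the
  raw scale; the raw-scale metrics are reported alongside for that reason.
* MAPE on log-scale values is ill-behaved when the truth crosses zero
  (log values near `log(offset)` change sign); the zero guard reports, but
  cannot repair, this.
* The windowed AMI at 150 points and 16 bins carries a few hundredths of
  a nat of positive bias; comparisons across days (the intended use) are
  unaffected, absolute values should not be over-read.
* Wavelet-based periodicity analysis and comparison against off-the-shelf
  forecasters (ARIMA, TBATS, TAR, Prophet) are out of scope.
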