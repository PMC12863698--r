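# mcml

Model-free forecasting and time-lagged analytics for epidemic-like daily
time series.

`mcml` is aimed at epidemiologists and quantitative analysts who need to
anticipate the progression of a univariate daily series — normalized
COVID-19 case counts, stock indices, insect population counts — without
fitting a parametric model to the raw data. It implements **maximum
correlation machine learning (MCML)**, a two-stage analog method, together
with the sliding-window diagnostics (autocorrelation, average mutual
information, local Lyapunov exponents) used to flag epidemic wave peaks as
they form.

## The method

Work on the log scale `Y_i = log(Z_i + 0.05)` and forecast the one-day
change `D_i = Y_i − Y_{i−1}`.

**Stage 1 — principal lags.** For `p = 2, …, q` (default `q = 19`) fit the
lagged linear models

```
D_i = a_0 + a_1 Y_{i−2} + … + a_p Y_{i−p−1} + ε_i
```

by OLS on a common set of `m` recent rows and pick `p*` minimizing
`BIC(p) = m log(rss/m) + (p + 2) log(m)`. The selected lag window
`Y(i−1) = (Y_{i−2}, …, Y_{i−p*−1})` is the *principal-lag vector* of day
`i − 1`.

**Stage 2 — maximum-correlation analog matching.** To predict `Y_{n}`,
find the historical anchor `i*` whose principal-lag vector is most
Pearson-correlated with the current one and reuse the increment that
followed it: `Ŷ_n = Y_{n−1} + D_{i*}`. For a multi-step forecast over a
held-out test block of length `M`, the query window slides forward using
previously predicted values while the analog search stays confined to the
training anchors; accuracy is scored by MAE, RMSE and MAPE.

**Time-lagged analytics.** Over a trailing sliding window (default 150
days, lag 15) the package tracks new cases `nc`, windowed autocorrelation
`ac` and binned average mutual information `ami`, rescales them onto a
common range with the *dynamic* scaling
`ac_scaled = (ac + 1) · max(nc_wl)/2`, `ami_scaled = ami · max(nc_wl)/2`,
and computes local Lyapunov exponents
`λ_t = log(|x_{t+1} − y_{t+1}| / |x_t − y_t|)` for the three feature pairs.
Their per-day maximum (the MLE) spikes near instabilities of the
feature-space trajectory; `peak_spike_alignment()` reports how those spikes
relate to case peaks.

## Worked example

```r
library(mcml)

series <- preset_series("two-wave", seed = 7)   # synthetic epidemic curve
fit <- mcml_run(series, train_frac = 0.8, q = 19)
fit
#> MCML run on 'series': N = 448 train, M = 112 test, p* = 2
#>   log-scale MAE = 0.3308, RMSE = 0.4367, MAPE = 0.3480

head(tidy(fit), 3)
#> # A tibble: 3 x 7
#>   date        step y_true y_pred i_star   rho  d_pred
#>   <date>     <int>  <dbl>  <dbl>  <int> <dbl>   <dbl>
#> 1 2021-03-24     1   3.61   3.64    280     1  0.0121
#> 2 2021-03-25     2   3.54   3.44    440     1 -0.199
#> 3 2021-03-26     3   3.44   3.35    428     1 -0.0926
```

The one-row summary says the BIC chose 2 principal lags on this smooth
two-wave curve and that the analog forecast tracks the held-out 112 days
with a log-scale MAE of 0.33. Each prediction row names the training
anchor `i_star` whose window matched (here with correlation ≈ 1) and the
historical increment `d_pred` that was reused. `autoplot(fit)` draws the
observed/predicted overlay; `autoplot(fit$selection)` the BIC curve.

The early-warning diagnostics on the same series:

```r
feats  <- sliding_features(series, window = 150, lag = 15)
scaled <- dynamic_scale(feats)
lyap   <- max_lyapunov(scaled)
peak_spike_alignment(tibble::tibble(date = scaled$date, value = scaled$nc),
                     lyap)
#> # A tibble: 3 x 3
#>   nc_peak_day mle_spike_day lead_days
#>   <date>      <date>            <dbl>
#> 1 2020-07-19  2020-07-10            9
#> 2 2020-12-25  2020-12-28           -3
#> 3 2021-01-16  2021-01-16            0
```

Two of the three detected case peaks had an MLE spike at or before the
peak (leads 9 and 0 days).

A shell interface wraps the same functions:

```sh
exec/mcml simulate --preset two-wave --seed 7 --out fixture.csv
exec/mcml forecast --input fixture.csv --train-frac 0.8 --out run.json
```

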