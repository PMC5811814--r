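# adamsim

Agent-based simulation of one-shot judgmental forecasting and average
estimation from monthly salary series, built around the **adaptive
anchoring model (ADAM)**. The package is for computational
cognitive-modeling work on trend damping — the robust human tendency to
under-predict rising series and over-predict falling ones — and on how the
*presentation mode* of a series (static all-at-once vs. dynamic
month-by-month) shifts what people anchor on.

## The model

A behavioral response to a presented series is

```
BR = SW × EA × (1 + kp · xp),        SW = exp(−(S − T))
```

* `S` — idealized stimulus item: 0.35 (the normalized series mean) for
  static presentation; the normalized last value for historic- or
  momentary-dynamic presentation.
* `T` — idealized task item: 0.35 for average estimation; the normalized
  last value for forecasting. Normalization divides pounds by 10,000.
* `EA` — experience-dependent anchor: 3,500 (the series mean) for static
  presentation; the last presented value for dynamic presentation.
* `xp` — standard-normal perceptual noise scaled by `kp` (default 0.04),
  so `E[BR] = SW·EA` and `SD[BR] = SW·EA·kp`.

Stimuli are 48-month series from `Y(t) = 3000 + 21.28t + n` (rising),
`Y(t) = 4000 − 21.28t + n` (falling) or `Y(t) = 3500 + n` (stationary),
with Gaussian noise of variance 10; *inconsistent* variants append a 49th
value of exactly 3,500. Baseline forecasters — the noisy
regression-predicted next trend value, AR(1) by conditional least squares,
and simple exponential smoothing — respond to the same series, and a
statistical harness (pooled t with effect size `r`, Levene's test,
SD-ratio, ε² factorial ANOVA, split-half cross-validation) compares them.

## Worked example

The deterministic core (`kp = 0`, noise-free rising series) has closed
forms, printed by `adam_demo()`:

```
              mode     task        S        T        SW      EA       BR reference signed_error
            static forecast 0.350000 0.402144 1.0535274 3500.00 3687.346   4042.72    -355.3740
  historic_dynamic forecast 0.402144 0.402144 1.0000000 4021.44 4021.440   4042.72     -21.2800
 momentary_dynamic forecast 0.402144 0.402144 1.0000000 4021.44 4021.440   4042.72     -21.2800
            static judgment 0.350000 0.350000 1.0000000 3500.00 3500.000   3500.00       0.0000
  historic_dynamic judgment 0.402144 0.350000 0.9491922 4021.44 3817.119   3500.00     317.1194
 momentary_dynamic judgment 0.402144 0.350000 0.9491922 4021.44 3817.119   3500.00     317.1194
```

Read row-wise: a static forecaster anchors on the mean (3,500) and damps
the trend, missing the true next value 4,042.72 by −355; a dynamic
forecaster anchors on the last value and misses by only one slope step
(−21.28). For average estimation the pattern flips: static estimation is
exact, dynamic estimation overshoots by +317. That fourfold dissociation
is the model's central prediction.

The full stochastic design, with the comparator forecasters on the same
series:

```r
library(adamsim)
tab <- run_full_design(adam(kp = 0.04), n_per_condition = 90,
                       models = c("adam", "arima_100", "exp_smoothing"),
                       tasks = "forecast", master_seed = 1)
summarize_design(tab)   # per-cell means/SDs; rising consistent cells:
#>              mode         model mean_signed sd_response
#>  historic_dynamic          adam   -24.07302    143.1899
#>            static          adam  -324.88798    155.7169
#>  historic_dynamic     arima_100     0.23610      3.4794
#>  historic_dynamic exp_smoothing   -21.22241      3.1969

unrelated_t(tab$response[tab$model == "arima_100"],
            tab$response[tab$model == "exp_smoothing"])
#> t(3238) = -0.001, p = 0.9991, r = 0.000
```

ADAM damps (−325 static, −24 dynamic) with SD ≈ `kp`·mean ≈ 143; the
trend-following comparators track the next value or the last value with
only the series noise, and their pooled forecasts are statistically
indistinguishable (`r = .00`).

A command-line front end with `simulate`, `compare`, `demo` and `report`
subcommands lives at `inst/cli/adamsim.R`:

```sh
Rscript inst/cli/adamsim.R simulate --n 90 --master-seed 7 --out runs/
Rscript inst/cli/adamsim.R compare --model-a adam --model-b arima_100
```

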