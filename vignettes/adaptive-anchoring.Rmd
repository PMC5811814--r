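---
title: "Adaptive anchoring: simulating one-shot forecasts and average estimates from time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive anchoring: simulating one-shot forecasts and average estimates from time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adamsim)
```

## The behavioral phenomenon and the model

People who forecast the next value of a time series systematically damp
trends: they under-predict rising series and over-predict falling ones. How
strongly they damp depends on how the series was experienced. When all
values are seen at once (static presentation), responses gravitate toward
the series average; when values are experienced one month at a time
(dynamic presentation, with or without the history remaining visible),
responses anchor on the most recent value. The same anchoring has opposite
consequences for the two one-shot judgments studied here: it *improves*
next-value forecasts (recent values are close to the true next value of a
trended series) and *worsens* estimates of the series average.

The adaptive anchoring model (ADAM) captures this with three ingredients.
An idealized stimulus item $S_i$ encodes how the series was experienced:
$S = 0.35$ (the normalized series mean) under static presentation, and the
normalized last value under either dynamic presentation. An idealized task
item $T_k$ encodes what is asked: $T = 0.35$ for average estimation, the
normalized last value for forecasting. Their signed mismatch sets a
similarity weight

$$SW = e^{-(S - T)},$$

deliberately *not* using the absolute distance, so the direction of the
stimulus–task mismatch survives into the response. The behavioral response
is then

$$BR = SW \times EA \times (1 + k_p x_p),$$

where the experience-dependent anchor $EA$ is 3,500 (the series mean)
under static presentation and the last presented value under dynamic
presentation, $x_p$ is a standard-normal perceptual-noise draw, and $k_p$
scales individual variability. A response is thus an anchor, stretched or
shrunk by how well the experienced stimulus matches the task, with
multiplicative Gaussian noise: $\mathrm{E}[BR] = SW \cdot EA$ and
$\mathrm{SD}[BR] = SW \cdot EA \cdot k_p$.

With `kp = 0` the model is fully deterministic and its predictions have
closed forms, which anchor most of the test suite:

```{r demo}
adam_demo()
```

The fourfold accuracy dissociation is visible directly in this table:
dynamic forecasts miss the true next value (4,042.72) by only one slope
step, static forecasts by ±355; static average estimates are exact, while
dynamic estimates are off by ±317.

## The stimulus series

Stimuli are monthly salary series of 48 values from one of three
generating equations — rising ($3000 + 21.28t + n$), falling
($4000 - 21.28t + n$) or stationary ($3500 + n$), $t = 1,\dots,48$, with
Gaussian noise $n$ of mean 0 and variance 10 (pounds²). *Inconsistent*
variants append a 49th value of exactly 3,500, breaking the trend;
*consistent* variants stop at 48. The generator (`trend_spec()`,
`generate_series()`) is seedable and exposes the noise variance as a
parameter.

Interpretation choices worth stating explicitly:

* **"Variance = 10" is read literally as a variance** (SD ≈ 3.16 pounds),
  not an SD, and is exposed as `noise_variance` for sensitivity analyses:
  it is very small relative to the 1,000-pound span of the trended series,
  so the trend is essentially deterministic at the default.
* **The appended 49th point carries no noise.** It names a single value
  (3,500), not a distribution, so it is generated exactly.
* **Months are indexed 1..48.** Under this indexing the deterministic mean
  of the trended series is 3,521.36 (rising) or 3,478.64 (falling), not
  3,500; the average-estimation reference is nonetheless fixed at 3,500
  for *all* series (see below). No alternative 0-based indexing switch is
  provided: since the judgment reference is a constant rather than a
  per-series realized mean, such a switch would have no consumer anywhere
  in the pipeline, and the 21-pound discrepancy is part of the modelled
  task environment rather than something to correct.

## Normalization and the model constants

The normalization that maps pounds into the unit interval is division by a
constant, 10,000 by default — the unique linear map sending the stated
series mean (3,500) to the stated item value (0.35). Per-series min–max
renormalization was rejected because it could not reproduce that
correspondence. The constant is exposed (`normalization`) together with
the coupled pair `static_stimulus`/`static_anchor`; the constructor
enforces `static_stimulus == static_anchor / normalization` so the two
representations cannot drift apart. The static items are fixed at 0.35
even for inconsistent series (whose realized mean differs slightly from
3,500): the constants are defined unconditionally, and conditioning them
on the realized series would quietly change the model.

`kp` defaults to 0.04, the perceptual-variability coefficient imported
from earlier memory-based scaling work; it is a model *input* here, not a
fitted quantity. `estimate_kp()` inverts the variance identity
($SD/mean = k_p$ within a cell) to check that simulated output is
consistent with the coefficient that generated it — a parameter-recovery
diagnostic, not a fit to human data.

One $x_p$ draw is taken per simulated response: each replicate stands for
one participant making one judgment, which is what "individual perceptual
variability" motivates. An alternative would be one draw per
(participant, series) pair shared across tasks; at the default design both
tasks are simulated independently per cell, so the distinction is
immaterial to any statistic computed here.

## The simulated experiment

`run_full_design()` crosses 3 presentation modes × 3 trend directions × 2
consistency levels for both tasks (36 cells), 90 replicates per cell by
default, mirroring a between-subjects design of 1,620 responses per task.
Two dependent variables are scored:

* **Forecast error** = response − regression-predicted next trend value.
  For consistent cells the reference is the generating equation evaluated
  at month 49 (the true model of the stimulus); for inconsistent cells,
  whose appended point breaks that model, an ordinary least-squares line
  is refitted to all 49 presented points and evaluated at month 50.
* **Estimation error** = response − 3,500. The reference is the same
  constant for all series.

Each replicate regenerates the series noise by default, so the
deterministic comparators also vary within a cell; `fixed_series = TRUE`
freezes one series per cell instead (variability from $x_p$ only). All
models requested for a cell respond to the *same* replicate series, so
model contrasts are never confounded with stimulus noise. Seeding is
hierarchical: a master seed deterministically yields one child seed per
cell, and within a cell the replicate series are drawn before any model
noise streams, so (a) any cell can be replayed in isolation from the run
metadata and (b) the stimuli are bit-identical whichever model subset is
requested.

## Comparator forecasters

Three baselines respond in the forecasting cells only:

* **Noisy regression next value** (`regression_next`): the reference
  forecast itself, weighted by the same multiplicative noise process
  $(1 + k_p\xi_p)$ as the behavioral model.
* **AR(1)** (`arima_100`): $y_t = c + \phi y_{t-1} + \varepsilon_t$ fit by
  conditional least squares — the exact least-squares regression of $y_t$
  on $y_{t-1}$, chosen over likelihood maximization because it is
  deterministic, has a closed form, and is directly testable against a
  brute-force minimizer of the conditional sum of squares; full ML via
  `stats::arima` remains available (`method = "ml"`). A series constant to
  machine precision forecasts the constant.
* **Simple exponential smoothing** (`exp_smoothing`): level
  $\ell_t = \alpha y_t + (1-\alpha)\ell_{t-1}$, initialized at the first
  observation, with $\alpha$ minimizing the in-sample one-step sum of
  squared errors over $[0.01, 0.99]$ (golden-section search, tolerance
  $10^{-8}$); the forecast is the final level. The simple (non-trended)
  flavor is the minimal cited form; damped-trend variants are out of
  scope.

ARIMA and smoothing forecasts are pure model forecasts by default; a flag
(`comparator_noise`) adds the multiplicative noise for sensitivity checks.

## Statistical harness

Model–data and model–model contrasts use Student's pooled-variance
unrelated t test (the equal-variance form is licensed by Levene's test,
center = mean, which is also exported), with effect size
$r = \sqrt{t^2/(t^2 + df)}$ — the only formula that reproduces the
conventional (t, df, r) pairings for this test. The factorial ANOVA
reports $\varepsilon^2 = (SS_\text{effect} - df\,MS_\text{error}) /
SS_\text{total}$ per effect; $\varepsilon^2$ has variants, and this
less-biased sums-of-squares form is the one implemented. Degenerate
conventions are explicit: a constant response reports all $F = 0$,
$p = 1$, $\varepsilon^2 = 0$; unbalanced or empty cells are an error
(the simulated design is always balanced); a single-record cell reports
SD = 0 in summaries. `split_half_check()` implements the cross-validation
of fit: each 90-response cell is halved at random and a 2 × 2 ANOVA
(series × subsample) should show neither a series main effect nor an
interaction when two samples come from the same process.

## What passing tests do and do not show

The generator emulates the *stimulus* side of the behavioral experiment
exactly — the design cells, series equations, lengths and the appended
inconsistent value. It does not emulate human responders: no response-scale
clipping, no rounding to whole pounds (the response device was
continuous), no inter-individual parameter spread beyond $k_p$, and no
distinction between historic- and momentary-dynamic experience — the model
defines identical items and anchors for both, so it structurally cannot
reproduce contrasts between those two modes. Passing tests therefore show
that the implementation honors the model's algebra and its documented
stochastic contracts, not that the model is an accurate account of any
particular human dataset.

One structural property deserves emphasis. The two trended series are
exact mirror images about 3,500 (the falling series is 7,000 minus the
rising one, appended point included), and both the AR(1) and smoothing
forecasters are equivariant under that reflection, so their forecasts pool
to the stationary level across the full design and the pooled
AR(1)-versus-smoothing contrast is near zero by construction — the
acceptance suite computes it at $r \approx .00$. The anchoring model's
only pooled asymmetry is the convexity of $e^{-(S-T)}$, worth well under a
pound against a pooled SD of hundreds, so its pooled contrast with the
trend-following comparators is also near zero in this implementation.
Large model differences live in *per-cell* contrasts (static and
inconsistent cells especially), which `compare`-style per-cell output
exposes; the pooled two-sample t is an insensitive summary of them in a
symmetric design.

## Problem sizes and numerical tolerances

The shipped tests run the design at its standard size (90 replicates per
cell, 1,620 pooled forecasts per model) for the model-comparison checks;
Monte-Carlo contracts use $10^4$ draws per cell (mean within 1%, SD within
3%), calibration checks use 1,000 repetitions (type-I error 5% ± 2%), and
noise-variance convergence uses 12,000 draws at 5% tolerance. Oracle
equivalence for the AR(1) fit is asserted to $10^{-6}$ on the forecast
against an independent profiled line-search minimizer; exponential
smoothing is asserted to machine tolerance against hand-unrolled
recursions. All stochastic tests fix their seeds; the acceptance script
takes its single seed from the command line and derives every stream from
it.
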