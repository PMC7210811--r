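---
title: "Thermal-time analysis of cold-stratified seed germination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-time analysis of cold-stratified seed germination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalgerm)
```

## The model

Germination of a non-dormant seed is driven by accumulated thermal time
(degree-days). Between a base temperature $T_b$ and the optimum, the
germination rate of the $g$-th population percentile is linear in
temperature,

$$\frac{1}{t_g} = \frac{T - T_b}{\theta_g},$$

where $t_g$ (days) is the time for $g$ percent of the seeds to
germinate and $\theta_g$ (°Cd) is the percentile's thermal-time
constant. Regressing $1/t_g$ on incubation temperature over the
sub-optimal range therefore gives a line whose x-intercept estimates
$T_b$ and whose reciprocal slope estimates $\theta_g$. Species with
morphophysiological dormancy, such as *Gentiana lutea*, only express
this behaviour after sufficient cold stratification; the package's
estimation chain treats conditions with too little germination for the
regressions (short stratifications) as "not estimable" rather than as
errors, because that outcome is itself informative.

The chain implemented in `thermal_time_analysis()` is:

1. **Pooled curves** (`pool_curve()`): replicate dishes of one
   site × stratification × temperature condition are pooled; cumulative
   germination is expressed as a fraction of the *filled* seeds
   (cut-test empties excluded), matching how final percentages are
   computed. Percentiles of the seeds that eventually germinated are
   available as an alternative basis (`basis = "germinated"`).
2. **Percentile times** (`percentile_times()`): $t_g$ for
   $g = 10, 20, \dots, 90\%$ by linear interpolation of time against
   cumulative percentage between the bracketing observations.
3. **Rate regressions** (`fit_rate_regression()`): OLS of $1/t_g$ on
   temperature per percentile; at least three temperatures are required.
4. **Sub-optimal range selection** (`select_suboptimal_range()`): every
   candidate upper temperature is tried; the one minimising the pooled
   residual variance (total SSE across percentiles over pooled residual
   df, on the rate scale) wins, ties going to the wider range.
5. **Base temperature** (`estimate_Tb()`): mean ± SD of the x-intercepts
   of the percentile regressions with a positive slope significant at
   $\alpha = 0.05$ (two-sided t test on the slope).
6. **Thermal time** (`constrained_thermal_time()`): each percentile is
   refitted through $T_b$ (least squares through the origin of $1/t_g$
   on $T - T_b$, slope $b = \sum xy / \sum x^2$) and
   $\theta_g = 1/b$; $\theta_{50}$ is the headline value, rounded to
   integer °Cd only for reporting.

## Design choices where the method is underdetermined

* **Pooling before interpolation.** Percentile times are interpolated
  from the pooled curve of the four dishes, not per dish: percentile
  times per dish are undefined whenever a dish stalls below the
  percentile, and pooling is the convention that keeps $t_g$ defined
  exactly when the condition as a whole attains $g$.
* **Candidate ranges.** By default every temperature with attained
  percentiles from the third-lowest upward is a candidate upper bound,
  so the data decide how far the linear range extends; the selection
  statistic is pooled across percentiles (a per-percentile choice would
  let single noisy percentiles fragment the range).
* **Which percentiles enter $T_b$.** All attained percentiles are fitted
  and availability decides: sparse conditions contribute few or no
  qualifying percentiles, dense ones up to all nine.
* **SD of $T_b$** is the sample SD (n−1) across qualifying percentiles.
* **Exact percentile hits** take the earliest observation at that value
  (germination is scored when first seen); interpolation below the
  first observation uses the origin (0 days, 0 %).

## Inference

`fit_proportion_glm()` fits a logit-link quasi-binomial GLM of per-dish
final germination (weights: filled seeds) on stratification,
temperature and locality with all interactions, and reports the
sequential (type-I) analysis of deviance with F tests on the empirical
dispersion (Pearson $\chi^2$/df) — the appropriate test family when the
dispersion is free. IRLS runs to a deviance tolerance of 1e-8 within
100 iterations; fitted proportions at the boundary raise a separation
flag. `pairwise_bonferroni()` compares stratification levels with
pooled-SD t tests, multiplying raw p-values by the number of
comparisons. `compare_Tb()` contrasts per-percentile x-intercepts
between conditions with a log-link quasi-Poisson GLM; since a log link
cannot accept the negative $T_b$ estimates that long stratification
produces, the values are shifted by $1 + |\min|$ first — the shift is
reported and warned about because the comparison then lives on a
shifted scale. This is the one place the procedure is not well defined
without an extra convention, and the shift is ours.

## The synthetic-data generator

`simulate_germination()` draws per-seed fates under known ground truth
so every estimator can be checked against the parameters that generated
its input:

* a seed is empty with probability `p_empty` (default 0.05);
* a filled seed is released from dormancy with probability
  `plogis((s - strat_half)/strat_slope)` after `s` days of cold
  stratification (defaults `strat_half = 55` d, `strat_slope = 12` d,
  chosen so that 0/15/30/60/90-day stratifications release roughly
  1/3/11/60/95 % of seeds, the qualitative pattern of a species needing
  two months of chilling);
* seed-to-seed thermal time is lognormal with median
  `theta50_true = 120` °Cd and log-SD `sigma_theta = 0.2` — the
  distributional family is a modelling choice (it guarantees
  positivity), and the spread is a calibration choice, not a measured
  quantity;
* between `T_b_true` (default 1 °C) and `T_opt_hi` (20 °C) a released
  seed germinates at $t^* = \theta_{seed}/(T - T_b)$; above the
  optimum the germinable fraction declines linearly to zero at
  `T_ceiling` (26 °C) while the rate stays at its plateau value — the
  simplest mechanism that reproduces the collapse of germination at 25
  and 30 °C;
* events are recorded at the first scheduled observation day
  $\ge t^*$; the default schedule is a Mon/Wed/Fri pattern to 98 days.

Determinism: each dish gets its own substream seed derived from the
root seed, so outputs are bit-for-bit reproducible and independent of
which subset of dishes is simulated together.

What the generator does **not** emulate: secondary dormancy,
after-ripening, seed ageing during the test, between-dish heterogeneity
beyond binomial sampling, and any interaction between stratification
and the thermal-time distribution (the real species shows a lower
$T_b$ after longer stratification; the generator has a single fixed
$T_b$). Passing parameter-recovery tests therefore demonstrates that
the estimation chain is consistent for the model it assumes — not that
the model captures every feature of real seed lots.

`simulate_soil_temperature()` models a logger buried at ~3 cm as an
annual sinusoid (minimum in mid-January) plus a small diurnal cycle
plus AR(1) noise, with a snowpack clamp: readings below the clamp band
are replaced by uniform draws inside it, reproducing the flat near-0 °C
winter plateau of snow-covered soil. The `soil_params_mountain()`
preset (annual mean 9.1 °C, amplitude 9 °C, diurnal 0.5 °C, noise SD
0.8 °C, autocorrelation 0.8, clamp band [−0.5, 1.5] °C, 24 readings/day
over three years from 01 Aug 2013) was calibrated once so that the
three Aug–Jul windows average ~75–80 days with daily means ≤ 2 °C,
the regime of the mountain grassland sites it emulates. The diurnal
amplitude is deliberately small: shallow burial and snow cover damp
the day/night swing, and a large diurnal term would push winter nights
below the clamp trigger and bias winter daily means upward. The
sinusoidal shoulder seasons are smoother than real logger traces, so
projected counts under large increments fall off somewhat faster than
observed ones; the classification of scenarios (full / partial /
insufficient release) is the robust output.

## Climate projection

`apply_scenarios()` adds each RCP increment (RCP2.6 +0.3/+1.7, RCP4.5
+1.1/+2.6, RCP6.0 +1.4/+3.1, RCP8.5 +2.6/+4.8 °C) to every reading —
equivalent to shifting daily means, for an additive constant —
recomputes daily means, and counts days at or below the threshold per
annual window. The dormancy-release band of 1 ± 1 °C is
operationalised by its upper bound, a threshold of 2.0 °C on the daily
mean. Windows default to consecutive 12-month spans from the first
date of the series (Aug–Jul for an August start), and cold days are
counted anywhere in the window, not required to be consecutive. The
outcome classes follow the germination evidence: ≥ 60 cold days permit
full dormancy release, 30–60 partial release, < 30 days are
insufficient.

```{r projection, eval = FALSE}
soil <- simulate_soil_temperature(soil_params_mountain(rng_seed = 1))
apply_scenarios(soil)
```

## Numerical notes and problem sizes

Degenerate inputs are handled explicitly: conditions with all-empty
dishes are undefined-result errors; percentiles above the final
germination are flagged unattained, not extrapolated; regressions with
fewer than three points are unavailable rather than fatal; a
non-positive constrained slope leaves $\theta_g$ undefined for that
percentile; tied candidate ranges resolve to the wider one. Reported
percentages use two decimals and $\theta$ integer °Cd; full precision
is kept internally.

The shipped tests run parameter recovery on 10,000 simulated seeds
(four sub-optimal temperatures, daily scoring), where the chain
recovers $T_b$ to well within 0.5 °C and $\theta_{50}$ within 10 %;
the Monte-Carlo power checks use 200 replicates of small designs, and
the projection property suite uses 100 one-year series at 4 readings
per day. These sizes give stable checks at interactive runtimes.

## Limitations

The ceiling temperature is not estimated (supra-optimal data are
excluded by range selection, as in the underlying method); hydrotime
and hydrothermal-time extensions are out of scope; the quasi-Poisson
comparison of $T_b$ inherits the shifted-scale caveat above; and the
bundled *G. lutea* summary table carries only condition-level means and
SDs, so dish-level reanalysis of the real experiment requires the
original scoring records.
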