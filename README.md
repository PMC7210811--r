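# thermalgerm

Thermal-time analysis of seed germination after cold stratification.

Mountain species with morphophysiological dormancy — the motivating case
is *Gentiana lutea* on Mediterranean mountains — need a long period of
cold, snow-covered soil before their seeds can germinate. Shorter,
warmer winters therefore threaten them twice: dormancy may never be
released, and the thermal-time budget for germination may not be met.
`thermalgerm` is for seed ecologists who run stratification ×
temperature germination trials and want to (i) estimate the thermal
thresholds of germination, (ii) test treatment effects with the
appropriate overdispersed models, and (iii) project how many
dormancy-releasing cold days future winters will offer under IPCC RCP
warming increments.

## The model

For the *g*-th percentile of a non-dormant seed population, germination
rate is linear in temperature over the sub-optimal range:

    1 / t_g  =  (T − T_b) / θ_g

where `t_g` (days) is the time to reach *g* % cumulative germination,
`T_b` (°C) is the base temperature and `θ_g` (°Cd) the thermal-time
constant. The package pools replicate dishes into cumulative curves on
a filled-seed basis, interpolates `t_g` for g = 10…90 %, fits the rate
regressions per percentile, selects the sub-optimal temperature range
by smallest pooled residual variance, estimates `T_b` as the mean
x-intercept of the significant percentile regressions, and recovers
`θ_g` from refits constrained through `T_b`. Quasi-binomial GLMs (F
tests on the empirical dispersion) and Bonferroni pairwise t tests
handle inference; a soil-logger module counts days at or below 2 °C
(the upper bound of the 1 ± 1 °C dormancy-release band) per annual
window under each RCP increment. A synthetic-data generator with known
ground truth backs every stage with parameter-recovery tests. See the
methods vignette (`vignettes/thermal-time-germination.Rmd`) for the
full account.

## Worked example

Simulate the full two-locality trial (2 sites × 5 stratifications ×
6 temperatures × 4 dishes × 25 seeds) under a ground truth of
`T_b = 1 °C`, `θ50 = 120 °Cd`, then run the analysis:

```r
library(thermalgerm)

records <- simulate_germination(germination_design(), sim_params(rng_seed = 1))
head(subset(final_germination(records), site == "IS" & pretreatment_days == 90))
#>    site pretreatment_days temperature_c n_dishes mean_pct sd_pct
#> 25   IS                90             5        4     95.4   6.75
#> 26   IS                90            10        4     94.8   2.09
#> 27   IS                90            15        4     97.9   2.41
#> 28   IS                90            20        4     98.0   2.31
#> 29   IS                90            25        4     20.4   8.49
#> 30   IS                90            30        4      0.0   0.00

thermal_time_analysis(records)
#> Thermal-time analysis (10 conditions)
#>  site pretreatment_days Tb_mean Tb_sd suboptimal_max theta50_cd
#>    IS                 0      NA    NA             NA         NA
#>    IS                30      NA    NA             NA         NA
#>    IS                60    1.51  0.14             15        143
#>    IS                90    1.10  0.09             15        120
#>    TM                60    0.99  0.28             15        149
#>    TM                90    0.75  0.15             15        126
#>  ...
```

Short stratifications (0–30 d) leave too few non-dormant seeds for any
percentile regression — their `T_b` is reported as unavailable, exactly
the behaviour seen in real trials of species requiring ≥ 60 d of
chilling. After 90 d the estimates recover the simulator's ground
truth closely (`T_b` ≈ 0.8–1.1 °C vs 1 °C; `θ50` ≈ 120–126 °Cd vs
120 °Cd); after 60 d the released fraction is only ~60 %, so the
filled-seed percentiles sit higher in the seed lot and `θ50` is
correspondingly larger.

Project dormancy-release feasibility from a simulated 3-year soil
logger series (calibrated mountain preset, Aug–Jul windows):

```r
soil <- simulate_soil_temperature(soil_params_mountain(rng_seed = 1))
apply_scenarios(soil)
#>     scenario delta_t mean_cold_days sd_cold_days         outcome
#> 1    Current     0.0           77.0         1.00    full_release
#> 2  RCP2.6-OP     0.3           67.7         1.53    full_release
#> 3 RCP2.6-LOP     1.7            9.0         1.73    insufficient
#> 4  RCP4.5-OP     1.1           42.7         2.31 partial_release
#> 5 RCP4.5-LOP     2.6            0.0         0.00    insufficient
#> 6  RCP6.0-OP     1.4           30.0         4.00 partial_release
#> 7 RCP6.0-LOP     3.1            0.0         0.00    insufficient
#> 8  RCP8.5-OP     2.6            0.0         0.00    insufficient
#> 9 RCP8.5-LOP     4.8            0.0         0.00    insufficient
```

Current winters offer ~77 days at or below 2 °C — enough for full
dormancy release (≥ 60 d). Only the optimistic RCP2.6 increment keeps
that status; +1.1 °C drops the count to the partial-release band
(30–60 d), and every less-optimistic pathway leaves fewer than 30 cold
days, too few for dormancy release to complete.

The package also ships the published condition-level germination
summary for *G. lutea* from the two Sardinian localities
(`gentiana_germination_summary()`, `gentiana_thermal_params()`), used
by the desk-scale checks and available for comparison with simulated
experiments.

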