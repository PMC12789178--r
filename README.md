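# nestclock

Chronotype — a consistent individual tendency to start daily activity
earlier or later than conspecifics — is easy to define and hard to measure
in the wild: diel timing shifts with day length, weather and breeding
stage, so raw onsets confound the individual with her environment.
`nestclock` implements, for incubating female songbirds monitored with
nest-temperature loggers, the full chain from raw logger exports to
selection analysis:

1. **Onset extraction** — parse 3-minute nest-temperature traces, find the
   start of nocturnal incubation, derive nest- and day-specific drop/rise
   thresholds, partition each day into on-/off-bouts, and take the start of
   the first off-bout after the night sit as the day's activity onset.
2. **Conspecific standardisation** — per date *i*,
   `z = (onset − mean_i) / SD_i` over all females measured that date
   (dates with < 3 females dropped; broods need ≥ 2 onsets), and the
   **chronotype** is a female's mean `z` over her first measured brood.
3. **Repeatability** — a Gaussian mixed model of `z` on Year × April day
   and breeding day (+ its square), with random intercepts for Female,
   Female-by-year and Nest-box; `r_across = V_F / V_total`,
   `r_within = (V_F + V_FY) / V_total`, with χ²(1) likelihood-ratio tests
   per component.
4. **Selection models** — a suite of GLM/LMMs
   (`response = C + C² + Year + C:Year + C²:Year + lay date + …`) for lay
   date, clutch size, hatchlings (estimated as `m + (c − m − u)/2`),
   fledglings, fledge success, second broods, female weight and nestling
   biometrics, reduced by backward elimination under marginality, with
   2000-draw simulated prediction bands.
5. **Synthetic data** — a seeded generator for logger traces, ambient
   series and breeding tables with known ground truth (latent chronotypes,
   programmed off-bouts, specified variance components and effect sizes),
   so every stage is verifiable by simulation.

It is a tidyverse-style package: functions take data frames first, return
tibbles, and fitted objects have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

A fully synthetic study: 164 females over three seasons, onset variance
components (female 0.15, female-year 0.06, nest-box 0, residual 0.79) and
a quadratic chronotype → lay-date effect of 4.095 days/z².

```r
library(nestclock)
library(dplyr)

cfg    <- sim_config(seed = 2025)
pop    <- simulate_population(cfg)
std    <- simulate_onsets(cfg, pop) |>
  standardise_onsets() |>
  filter_measurement_set()
chron  <- compute_chronotype(std, broods = pop$broods)

rep <- onset_repeatability(std)
glance(rep)
#>   r_within_year r_across_year logLik singular n_obs n_females n_female_years
#> 1         0.231         0.146 -2644. FALSE     1969       164            197
rep$tests
#>   term        statistic    df       p
#> 1 female          6.63      1 0.0100
#> 2 female_year    10.4       1 0.00128
#> 3 nest_box        0.324     1 0.569
```

The standardised onset is repeatable within years (r = 0.23) and across
years (r = 0.15): about a seventh of the phenotypic variance is a stable
individual signature, close to the generating values (0.21 / 0.15). The
nest-box component sits at the boundary, as expected with high site
fidelity confounding box and female.

```r
suite <- build_model_suite(chron, pop$broods, pop$nestlings, pop$condition)
tidy(stepwise_reduce(fit_selection_model(suite$lay_date)))
#>   response term                 kind statistic    df        p estimate    se retained
#> 1 lay_date chronotype_sq:year_f F        2.51       2 8.45e-2    NA     NA   FALSE
#> 2 lay_date chronotype_sq        F        0.0611     1 8.05e-1   -0.263   1.07 FALSE
#> 3 lay_date chronotype:year_f    F        0.534      2 5.88e-1    NA     NA   FALSE
#> 4 lay_date chronotype           F        0.111      1 7.40e-1    0.251   0.753 FALSE
#> 5 lay_date year_f               F       20.7        2 1.01e-8    NA     NA   TRUE
```

Each row is one deletion test on the reduction path (estimate ± SE taken
*before* the term was dropped); here only the year effect survives. Note
the quadratic lay-date effect injected into the simulation is *not*
recovered from measured chronotypes at this sample size — measurement
error in a ~10-onset chronotype attenuates a quadratic coefficient by
roughly the squared reliability — whereas the same suite applied to the
latent chronotypes (`truth_chronotypes(pop)`) recovers it; the acceptance
script quantifies this. `autoplot()` on any reduction draws the response
against chronotype with its simulated 95% band.

Detection from raw traces uses the same grammar:

```r
trace  <- parse_logger_export("nest42.csv", ambient = ambient_tbl)
start  <- detect_incubation_start(trace)
th     <- derive_thresholds(trace, dates)
bouts  <- detect_bouts(trace, th)
onsets <- extract_daily_onsets(bouts, brood_row)
```

`run_pipeline(pipeline_config(seed = 1))` executes
simulate → standardise → repeatability → fit → report into a run directory
with a checksum manifest and per-filter row-count log.

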