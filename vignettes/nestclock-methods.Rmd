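---
title: "Chronotype from nest temperatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronotype from nest temperatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestclock)
library(dplyr)
```

`nestclock` implements an analysis chain for female songbird chronotype —
the consistent tendency of an individual to start her daily activity earlier
or later than conspecifics — measured from nest-temperature loggers during
incubation and chick provisioning, and for asking whether that chronotype
predicts reproductive success and life-history traits. This vignette
documents the models, the algorithmic and numerical choices, and what the
simulation-based validation does and does not establish.

## From nest temperature to activity onset

An incubating female warms the nest far above ambient. When she leaves
(an *off-bout*) the nest cools toward ambient; when she returns (an
*on-bout*) it recovers. Loggers record every 3 minutes, quantised to the
device accuracy (0.0625 °C, or 0.5 °C when storage is traded for
deployment length). The daily *activity onset* is the start of the first
off-bout after the nocturnal sit.

Detection proceeds in four steps.

1. **Incubation start** (`detect_incubation_start()`). Nocturnal full
   incubation is visible as the night window (21:00–05:00, assigned to the
   calendar date containing each sample) sitting at least 5 °C above
   ambient for at least 75% of its samples. Onsets are extracted only from
   the first such date onward.
2. **Nest- and day-specific thresholds** (`derive_thresholds()`). A real
   departure must exceed the temperature variation the nest shows while the
   female sits. The drop threshold is the larger of a 0.5 °C floor and the
   95th percentile of absolute successive differences over that date's
   night window; the rise threshold is derived symmetrically from daytime
   plateau segments (samples ≥ 5 °C above ambient and within 1.5 °C of the
   date's daytime 90th percentile). Only time-consecutive sample pairs
   inside each window contribute, so window boundaries never inflate the
   quantile. Dates with fewer than 10 night samples fall back to the
   pooled nest-level threshold and are flagged.
3. **Bout scan** (`detect_bouts()`). A single pass over each day keeps a
   running baseline — the extremum of the trailing 15 minutes of the
   current bout. An off-bout opens at the first sample more than the drop
   threshold below the baseline, provided the nest is cooling *toward
   ambient* and the decline contains a recent fast step (≥ 0.75 of the
   threshold within one sample). The fast-step condition encodes the
   thermal physics: with an 8-minute cooling constant, a genuine departure
   of ≥ 2 °C amplitude loses more than half its amplitude in the first
   3-minute sample, whereas sensor noise almost never produces such a
   step. The bout start is then backtracked to the first sample of the
   sustained decline, which places the boundary within one sample of the
   true departure. Closure is symmetric, with an additional *absolute
   recovery* rule: the off-bout also ends as soon as the temperature is
   back within half a threshold of the pre-departure plateau (estimated
   robustly as the trailing-window median). Finally, "off-bouts" whose
   median temperature never leaves the plateau are folded back into the
   surrounding on-bout; they are single-sample noise excursions, not
   absences. Days containing a gap of two or more sampling intervals are
   invalidated, since a first-departure time would be ambiguous.
4. **Onset extraction** (`extract_daily_onsets()`). The onset is the start
   of the first off-bout after the longest nocturnal on-bout. Dates more
   than 13 days after (expected) hatch are excluded; when hatching is
   unobserved the expected hatch is clutch completion + 13 days (hatching
   on incubation day 14). Onsets may precede sunrise freely; no sunrise
   gating is applied.

The scan is deliberately simple enough to be checked against an exhaustive
brute-force re-derivation; the test suite verifies exact boundary equality
on randomized short traces, and round-trip recovery of programmed
departures within one sampling interval at both logger accuracies.

## Conspecific standardisation and chronotype

Raw onsets shift with day length and weather. Standardising within date
against the other females measured the same day removes everything shared
by the date:

$$z_{ij} = \frac{\text{onset}_{ij} - \overline{\text{onset}}_{\cdot j}}
{\text{SD}(\text{onset}_{\cdot j})}$$

Dates need at least three females, otherwise they are dropped (as are
zero-SD dates, where $z$ is undefined); broods need at least two retained
standardised onsets. A female's *chronotype* is the mean $z$ of her first
brood in her first measured year; later years stay in the data only for
repeatability estimation, so each female enters the selection models once.

The sample (n−1) SD is used by default: per-date samples are small, and the
unbiased denominator is the safer convention (`sd_type = "population"`
switches). Onsets from different breeding stages measured on the same date
are pooled in the date mean — between-stage differences are handled in the
mixed model through breeding day, not in the standardisation.

## Repeatability

The standardised onset is modelled with a Gaussian linear mixed model
(REML):

$$z = \text{Year} \times \text{AprilDay} + \text{BreedingDay} +
\text{BreedingDay}^2 + u_{\text{female}} + u_{\text{female:year}} +
u_{\text{nestbox}} + \varepsilon$$

April day and breeding day are centred before fitting for conditioning.
From the variance components,
$r_{\text{across}} = V_F / V_T$ and
$r_{\text{within}} = (V_F + V_{FY}) / V_T$ with
$V_T = V_F + V_{FY} + V_{NB} + V_R$. The nest-box share is typically
confounded with female identity and estimated at the zero boundary; such
boundary fits are flagged, not errors, and the finite-difference Hessian
check is skipped because it spuriously trips exactly at these legitimate
boundary solutions. Both denominators (with and without the nest-box
component) are reported, since with $V_{NB}=0$ they coincide and the choice
cannot be resolved from ratios alone.

Random components are tested by removing one intercept and referring twice
the REML log-likelihood difference to $\chi^2_1$. No 50:50 boundary mixture
is applied, which makes the test conservative for true zero components —
the calibration test confirms a rejection rate at or below the nominal 5%.
Fixed effects are tested by maximum-likelihood refits with single-term
deletions respecting marginality.

## The selection-model suite

Each fitness or life-history response is modelled as

$$\text{response} = C + C^2 + \text{Year} + C{:}\text{Year} +
C^2{:}\text{Year} + \text{LayDate}_c (+ \text{covariates})$$

with $C$ the chronotype and lay date centred within year. The suite
comprises: lay date (no lay-date covariate), clutch size, hatchlings and
fledglings (Gaussian); fledge success and second brood (binomial, the
latter restricted to successful first broods and adjusted for the first
brood's fledgling count); female body weight (Gaussian, with time of day,
its square, and tarsus); and nestling weight, tarsus and P3 feather length
(Gaussian mixed models with a brood random intercept, hatch date replacing
lay date, chick age and fledgling count as covariates, time-of-day terms
for weight). Deserting females are excluded from the hatchling, fledgling
and fledge-success models; pre-hatch failures additionally from fledge
success. Hatchling counts carry observation uncertainty:
$\hat{H} = m + (c - m - u)/2$ for clutch $c$, maximum observed nestlings
$m$ and unhatched eggs $u$, which bounds $m \le \hat{H} \le c - u$.
Single-year inputs (as in re-analyses of single-season datasets) drop the
year terms automatically.

Model reduction is backward elimination under marginality: a term is
droppable only while no retained higher-order term contains it
(interactions before main effects, quadratic before linear, including
$C{:}\text{Year}$ inside $C^2{:}\text{Year}$). At each step every droppable
term gets a single-term deletion test — F for Gaussian responses, the
(signed) deviance change for binomial, $\chi^2$ likelihood ratio for mixed
models — and the term with the largest $p \ge \alpha$ (default 0.05) is
removed, its estimate and standard error recorded from the model it was
dropped from. Covariates of no direct interest are droppable like any
other term; `force_retain` pins them if desired. Dropped terms are never
re-entered.

One calibration subtlety is worth making explicit. "The quadratic term is
retained" conflates two events: its own deletion test being significant,
and its protection by a retained $C^2{:}\text{Year}$ interaction (which
itself survives ~5% of null datasets). Presence-in-final-model therefore
has a null rate near $0.05 + 0.95 \times 0.05 \approx 0.1$ *by
construction*, not 0.05. The calibration test and the acceptance script
accordingly measure the type-I error of the quadratic term's own deletion
test — the fraction of suites whose recorded test has $p < 0.05$, among
suites where the term was actually tested — which is the quantity that
should match the nominal level.

Prediction bands (`simulate_prediction_band()`) draw 2000 coefficient
vectors from the asymptotic multivariate normal of the estimates, map each
through the linear predictor and inverse link, and take the 2.5% and 97.5%
draw quantiles — the standard simulation approach for GLM credible
intervals.

## The synthetic-data generator

The generator (`sim_config()`, `simulate_population()`,
`simulate_onsets()`, `simulate_ambient()`, `simulate_nest_temperature()`)
defines the study conditions under which the pipeline is validated:

* **Onset variance components** default to $V_F = 0.15$,
  $V_{FY} = 0.06$, $V_{NB} = 0$, $V_R = 0.79$ (summing to 1 on the
  standardised scale), i.e. across-year repeatability 0.15 and within-year
  0.21 — the regime of a moderately repeatable behavioural trait.
* **Latent chronotype** is Gaussian with SD 0.45, making per-female mean
  chronotypes span roughly ±1.2 standardised units. The female component
  of the onsets *is* the latent chronotype rescaled to variance $V_F$, so
  the same individual quantity drives both diel timing and, through the
  lay-date link, seasonal timing.
* **Lay date** responds to chronotype with a default quadratic effect of
  4.095 days/z² and linear 0.239 days/z over a residual SD of 5 days, with
  year offsets (0, +4, −2 days); clutch size declines by 0.055 eggs per
  day of within-year lay-date deviation. Chronotype effects on all other
  outcomes default to zero, which is the null the calibration tests rely
  on.
* **Population structure**: most females (84%) are measured in a single
  season, 12% in two and 4% in three (consecutive) seasons; nest-box
  fidelity across years is 73%, with boxes drawn from a pool 1.25× the
  population. The box-switching minority is what statistically separates
  nest-box from female variance.
* **Thermal model**: on-bouts relax toward a 35 °C plateau with a 4-min
  time constant; off-bouts decay toward ambient (or a programmed drop)
  with an 8-min constant; sensor noise is 0.1 °C (the scale of the fine
  logger step) before quantisation to the configured accuracy. Ambient is
  a diel sinusoid (coldest 04:00) sampled on a 30-min grid, as ambient
  reference loggers are binned in the field.
* **Heavy-tail contamination** of onsets (occasional extremely early
  departures) is available but off by default.

Determinism: one master seed is expanded into fixed per-stream sub-seeds,
so each table is individually reproducible and two runs with the same
configuration are byte-identical (the pipeline manifest checksums verify
this end-to-end).

What passing these simulations shows — and what it does not. The generator
produces clean square-wave departures, stationary sensor noise, no sensor
displacement, no weather-driven ambient excursions and no male
provisioning; recovery rates near 100% on synthetic traces are an upper
bound on field performance, where the thresholding rules (not re-tuned
here) have to absorb all of those. The variance-component recovery and
suite calibration, in contrast, exercise exactly the estimators used on
real data and transfer directly.

## Numerical choices and degenerate inputs

* Per-date z-scores are exactly mean-0, SD-1; pure power-of-two rescalings
  of the onsets leave z bit-identical, while shifted affine maps agree to
  within a unit in the last place (the date means re-round).
* Zero-SD dates are excluded rather than assigned $z = 0$.
* First broods are resolved by earliest lay date, then earliest incubation
  start, then lowest brood id.
* Trailing-window width for the bout baseline is 15 min (5 samples):
  longer than any single departure transient, far shorter than nocturnal
  drift time-scales.
* Binomial deletion tests store the signed deviance change
  (negative when dropping a term worsens the fit), with $p$ from
  $|\Delta|$ on $\chi^2$.
* Perfect separation in binomial fits yields a flagged result, not an
  error; all-zero responses fit as degenerate intercept-only models.
* Validation problem sizes: variance-component recovery uses 20 replicates
  of 200 females × 3 years × 10 onsets; suite calibration uses 500 null
  populations of 164 females plus 50 populations with the injected
  quadratic effect; detection round-trips use 100 programmed nest-days per
  logger accuracy. These sizes hold Monte-Carlo error comfortably below
  the tolerances being checked while keeping the whole suite fast.

## Known limitations

* The bout scan assumes fast departures; a female leaving during already
  cool, windy conditions with a slow nest-cooling rate could be missed at
  the 0.5 °C floor. Threshold and window are configurable per call.
* Within-year repeatability is defined as $(V_F + V_{FY})/V_T$; if
  female-by-year variance partly reflects nest-site rather than individual
  state, this reading overstates short-term individual consistency.
* Backward elimination never re-enters dropped terms, and $\alpha = 0.05$
  is a convention; the full reduction path is always recorded so any other
  stopping rule can be applied post hoc.
* The second-brood model conditions on first-brood success, so chronotype
  effects acting through success itself are not visible there.
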