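---
title: "Process-based bloom prediction and calibration in bloomcast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-based bloom prediction and calibration in bloomcast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

bloomcast predicts the full-bloom date (BBCH 65) of temperate fruit
trees from hourly winter temperatures by coupling two classic
submodels.

**Chill accumulation** follows the Dynamic Model: a precursor of the
dormancy-breaking factor (PDBF, level $x$) forms at rate
$k_0 = A_0 e^{-E_0/T}$ and decays at rate $k_1 = A_1 e^{-E_1/T}$
($T$ in Kelvin; the package uses the convention $T = t_{^\circ C} + 273$,
so the fixed optimal temperature $\theta^* = 279\,$K corresponds to
6 °C). Each hour the precursor relaxes toward its steady state
$x_s = (A_0/A_1)e^{(E_1-E_0)/T}$:

$$x' = x_s - (x_s - x)\,e^{-k_1}.$$

When $x'$ reaches 1, a fraction
$\xi(T) = s/(1+s)$ with $s = \exp\{\mathrm{slope}\cdot T_f (T - T_f)/T\}$
is banked as permanent chill ($y \mathrel{+}= \xi x'$, a Chill-Portion
variant) and removed from the precursor pool. Conversion happens at
most once per hourly step, after the kinetic update. $\xi$ equals 0.5
at $T_f$ and increases with temperature.

**Heat accumulation** follows the Growing Degree Hours model: a
piecewise-cosine response that is zero at or below the base
temperature $T_b$ and at or above the critical temperature $T_c$
(fixed at 36 °C), and peaks at $T_u$ with $T_u - T_b$ heat units per
hour. The stress factor of the original formulation is fixed at 1.

**Coupling.** Accumulated chill gates forcing through a logistic
weight $w = 1/(1+e^{-s_1(y - y_c)})$ centered on the cultivar's chill
requirement $y_c$; hourly heat is accrued as $w \cdot \mathrm{GDH}(T)$.
Bloom is predicted on the day containing the first hour at which the
weighted heat sum reaches the heat requirement $z_c$; if the season
ends first, the simulator records a failure to bloom. Large $s_1$
yields strictly sequential chill-then-heat phases; small $s_1$ lets
the phases overlap. No additional clamp is applied below the chill
requirement: the logistic tail is the model's own statement about
pre-chill forcing sensitivity.

The dormancy season defaults to 1 September (year $t-1$) through
30 June (harvest year $t$), configurable; this spans both
Mediterranean and temperate European dormancy and bloom ranges. Bloom
is reported at day granularity because observations are daily records.
Internally, days before 1 January carry non-positive day-of-year
values in the harvest year's frame; all I/O uses ISO dates.

## The intermediate parameterization of the chill submodel

The canonical kinetic parameters $(E_0, E_1, A_0, A_1)$ are poorly
bounded and strongly correlated, so calibration operates on four
narrowly bounded intermediate quantities: $\theta^*$ (optimal constant
chill temperature, fixed at 279 K), $\theta_c$ (critical constant
temperature above which no chill accumulates, 286–287 K), $\tau$
(hours to the first Chill Portion at $\theta^*$, 16–48 h) and $\pi_c$
(critical period of a combined temperature cycle at which chill
negation sets in, 24–50 h).

The mapping back to canonical form is solved numerically from defining
conditions rather than a transcribed closed form, which makes the
package robust to formula-transcription errors:

1. **Criticality:** $x_s(\theta_c) = 1$, so constant exposure at or
   above $\theta_c$ never completes a portion. This fixes $A_0/A_1$
   given $\Delta E = E_1 - E_0$. A one-ulp-down guard on $A_0$ keeps
   the inequality strict under floating point.
2. **Timing:** starting from $x = 0$ at constant $\theta^*$, $x$
   reaches 1 exactly at hour $\tau$. Because the hourly recursion
   compounds exponentially, the discrete and continuous trajectories
   agree at integer hours, so the first portion lands within
   $\pm 1$ h of $\mathrm{round}(\tau)$. This fixes $A_1$.
3. **Optimality:** the time-to-first-portion is minimized at
   $\theta^*$. Differentiating the closed-form portion time yields
   $E_1 = \Delta E\, u^*/[(1-u^*)(-\ln(1-u^*))]$ with
   $u^* = 1/x_s(\theta^*)$, tying $E_1$ to $\Delta E$. (With
   $\theta_c = 286.5$ K this relation reproduces the conventional
   default $E_1 = 9900.3$ to about 0.1 %, a strong consistency check.)
4. **Negation:** $\Delta E$ itself is pinned by $\pi_c$ through a
   square-wave cycle alternating spells at $\theta^*$ and at a warm
   negating temperature (297 K by default, configurable — the warm
   temperature is a convention of the cycle construction, not a fitted
   quantity). The cyclic steady-state precursor peak equals exactly 1
   when the cycle period equals $\pi_c$; a bracketing search plus
   `uniroot` solves for $\Delta E$.

The cold spell of the negation cycle is
$\min(\pi_c/2,\, 0.9\,\tau)$: a cold spell longer than $\tau$ would
complete a portion on its own, making negation impossible and the
critical period undefined. The cap keeps the construction well defined
and continuous over the entire admissible box; with it, every
combination in a 5×5×5 grid spanning the $(\theta_c, \tau, \pi_c)$
bounds solves and satisfies conditions 1–2 exactly (checked in the
test suite).

## Calibration schemes

All schemes estimate the three requirement parameters
$(y_c, z_c, s_1)$ per cultivar. They differ in the chill/heat
submodels:

* **baseline** — the standard submodel defaults
  ($E_0 = 3372.8$, $E_1 = 9900.3$, $A_0 = 6319.5$,
  $A_1 = 5.939917\times 10^{13}$, $T_f = 4$, slope $= 1.6$;
  $T_b = 4$, $T_u = 26$, $T_c = 36$): 3 free parameters per cultivar.
* **cultivar_fit** — everything re-estimated per cultivar: 10 free
  parameters each ($\theta^*$ and $T_c$ stay fixed).
* **combined_fit** — submodels shared across all cultivars of one
  species, requirements cultivar-specific: $3K + 7$ free parameters
  for $K$ cultivars. Combining cultivars across species is refused;
  run one calibration per species.

The objective is the RMSE (days) of predicted minus observed bloom
day-of-year pooled over all observations; pooling is unweighted, so
cultivars with more observations influence the shared submodel more.
A season that fails to bloom contributes a penalty residual of
(season-end DOY − observed DOY + 30) days: finite, dominating over
ordinary residuals, and decreasing as the model approaches blooming,
which keeps the search surface informative. Decoding or simulation
failures return a large finite penalty rather than raising, as
derivative-free optimizers require.

**Optimizer.** A seeded differential-evolution stage (rand/1/bin,
dithered amplification factor, reflection at the bounds) followed by
Nelder–Mead polish clamped to the box. One run per problem — no
multi-start. Exploiting separability: the baseline and cultivar-fit
objectives decompose by cultivar, so each cultivar's subproblem is
searched independently; the combined-fit scheme searches the joint
vector and then applies alternating block refinement (the 7 shared
parameters, then each cultivar's 3 requirements). Initialization is
uniform within the bounds from the problem seed; identical seeds give
bitwise-identical fits. The default budget (population scaled to
dimension, 200 generations) is sized for desk-scale experiments of a
few cultivars and a few dozen seasons.

## Evaluation protocol

`split_observations()` partitions per cultivar, randomly under a
recorded seed (the split rule is not chronological by default because
bloom records are approximately exchangeable across years; a
chronological option exists). Full mode assigns
round(0.75 n) observations to calibration (round-half-to-even);
scarce mode exactly 10. Cultivars too small to leave a validation
point are excluded with a warning. Metrics: RMSE; RPIQ, the
interquartile range of observations (linear-interpolation quartiles,
R type 7 — RPIQ depends on the quartile rule, so it is fixed and
documented) divided by RMSE; mean bias (predicted − observed); and
the proportion of absolute residuals above 7 days. Validation
predictions that fail to bloom are excluded from the metrics and
counted separately.

## The synthetic-data generator

`generate_weather()` emulates a mid-latitude orchard climate: a
sinusoidal annual cycle in daily mean temperature (coldest in
mid-January for the Northern Hemisphere — the sign convention places
the trough, not the crest, at the coldest-day offset), AR(1)
day-to-day noise, and a constant diurnal range split symmetrically
into tmin and tmax. Defaults (latitude 40°, annual mean 12 °C,
amplitude 11 °C, diurnal range 8 °C, AR(1) coefficient 0.6, innovation
sd 1.5 °C) describe a warm-autumn temperate site where chill
accumulates from late autumn and bloom falls in late March; these
values were fixed once as the package's standard study conditions.
`generate_bloom_observations()` simulates every cultivar × season
under a ground-truth parameter set and adds integer-rounded Gaussian
observation noise (bloom records are whole dates). The default truth
(`default_truth_spec()`) uses three cultivars with well-separated
requirements and species-shared submodels within the admissible
bounds.

What the generator does **not** emulate: weather measurement error and
station gaps, spatial heterogeneity, heat waves and cold snaps beyond
AR(1) noise, photoperiod effects, and any biological deviation from
the model family itself. Passing recovery tests therefore demonstrate
that the calibration machinery can invert the model's own data — a
"virtual ecologist" experiment — not that the model is correct for
real orchards.

`recovery_experiment()` packages the standard experiment: 25
calibration seasons per cultivar, 1-day observation noise, combined
fit at the default budget, validation on 8 additional held-out seasons
generated from the same climate (held-out years rather than a random
subsample, so validation probes temporal generalization).

## Numerical choices and degenerate inputs

* Kelvin conversion uses +273 exactly, so $\theta^* = 279$ K is 6 °C.
* The logistic conversion fraction and the chill-to-heat gate are
  evaluated in numerically stable form; both saturate to 0/1 in double
  precision a few tens of degrees from their midpoints.
* Empty temperature series yield empty trajectories (final chill 0 by
  convention); seasons shorter than 30 days are rejected as
  degenerate; non-finite temperatures are errors, not silently
  propagated NaNs.
* The temperature-response grid is −5.0, −4.9, …, 50.0 °C (551
  points) with 1200 h of constant exposure. The heat curve is
  normalized by its own maximum, so it peaks at exactly 1.0. The chill
  curve reports raw Chill Portions; because portions complete in
  discrete conversion events, the curve carries a sub-portion
  staircase ripple (≲ 0.5 CP) on top of its unimodal envelope, and
  tests assert unimodality up to that ripple.
* Gap filling: tmin and tmax are filled independently, each with its
  own moving-window bias estimate (window 15 days, ≥ 1 shared day
  required — the count is reported so stricter screening can be
  applied downstream). Among several auxiliary stations the one with
  most shared days in the window wins, ties broken by smaller
  absolute bias. Biases beyond ±3 °C or with sd above 3 °C are
  flagged, not refused. Auxiliary-station distance is metadata-level
  screening, not enforced numerically.
* Daily-to-hourly conversion uses the idealized diurnal curve standard
  in horticultural chill modelling: sine rise from sunrise to an
  afternoon peak, cosine easing to sunset, logarithmic decline
  overnight toward the next day's minimum, with sunrise/sunset from
  the standard solar declination and hour-angle equations. The peak is
  snapped to the sampled integer-hour grid so the day's hourly maximum
  equals tmax exactly.

## Known limitations

* **Equifinality.** The chill submodel's $\tau$ acts largely as a
  time-scale on accumulated chill, so $(\tau, y_c, s_1)$ can trade off
  against each other with almost no cost in bloom-date RMSE. At 1-day
  observation noise, distinct parameter sets fit synthetic data
  within a few hundredths of a day of each other while differing by
  tens of percent in $y_c$. Better optimization does not resolve
  this — it can even prefer the overfitted basin. Requirement
  estimates should be interpreted jointly with the temperature
  response curves, and the recovery experiment reports the actual
  relative errors rather than hiding them.
* Bloom-day predictions are integers, so the objective is piecewise
  constant; the evolutionary stage handles the plateaus, but local
  polish alone cannot.
* The hourly interpolation is an idealized clear-sky curve; advective
  weather breaks it.
* Only one phenological stage (full bloom) is modelled; no
  photoperiod, no frost damage, no multi-stage development.

## Problem sizes

The test suite and the acceptance script run desk-scale experiments:
oracle equivalence on 50 random 1200-h seasons, the full 125-point
reparameterization grid, response curves at the full 551-point grid,
and one recovery experiment with 3 cultivars × 25 seasons under the
default optimizer budget. These sizes were chosen as the smallest
configurations that exercise every contract meaningfully.
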