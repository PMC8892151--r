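---
title: "Measuring rumen fermentation kinetics from head-space pressure: models, conventions and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rumen fermentation kinetics from head-space pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasferm)
```

## The measurement problem

In vitro gas production (GP) assays ferment a feed sample in buffered rumen
fluid inside a sealed bottle and take the evolved gas volume as a proxy for
microbial degradation. What a pressure-based system actually observes is the
head-space over-pressure between vents. `gasferm` implements the full data
path of such a system — sensor calibration, cumulative pressure accounting,
ideal-gas conversion to volume, blank correction, kinetic model fitting and
repeatability statistics — together with a bottle simulator whose ground
truth is known, so every stage of the pipeline can be validated without
bench data.

Two measurement techniques are represented. The *automated* technique reads
36 bottle sensors every 15 min over 48 h (192 readings per bottle) and vents
immediately after every reading, so the head space never accumulates much
pressure. The *manual* technique reads a hand-held digital gauge and vents
at 2, 4, 6, 8, 12, 16, 24, 36 and 48 h only.

## Kinetic model

Cumulative GP per gram of incubated dry matter follows the
exponential-with-lag model

$$G(t) = B\,\bigl(1 - e^{-c (t - L)}\bigr), \qquad t \ge L,$$

with asymptote $B$ (mL/g DM), fractional rate $c$ (h$^{-1}$) and lag $L$
(h). For $t < L$ the raw expression is negative; `predict_gp()` clamps it to
zero, which is what a lag means biologically. Fitting
(`fit_kinetics()`) is bounded Levenberg–Marquardt least squares
($B, c, L \ge 0$, $L$ no later than the last observation), restarted from
three perturbed starting rates ($0.5\times$, $1\times$, $2\times$) because
exponential fits are initialization-sensitive; the lowest-RSS converged
solution is kept and is guaranteed not to be worse than the analytic
starting guess. Convergence tolerance is $10^{-8}$ on the relative
reduction and parameter step, with a 500-iteration cap per start.

## Pressure accounting and volume conversion

Each recorded reading is the over-pressure accumulated since the previous
vent; `cumulate_pressure()` forms the running sum. Readings in
$(-0.5, 0)$ kPa are clamped to zero before summing — noise around zero must
not make a cumulative curve non-monotone — while anything below
$-0.5$ kPa is treated as a sensor fault.

The ideal-gas conversion with head-space volume $V_0$ and atmospheric
pressure $P_{atm}$ admits two conventions:

* **gross**: $(P_1 + P_{atm})\,V_0 / P_{atm}$, the bottle's total gas
  content referred to ambient pressure — equal to $V_0$ at zero
  over-pressure;
* **net**: $P_1 V_0 / P_{atm}$ = gross $-\,V_0$, the evolved gas alone.

Net is the default: GP must be zero at the start of an incubation, and the
$V_0$ offset cancels under blank subtraction anyway. Both are implemented
because published conversion formulas are usually printed in the gross
form. $P_{atm}$ is a per-run constant (default 101.325 kPa), read once at
the start of a run; the simulation is isothermal at 39 °C and temperature
never enters because only pressure ratios are used.

Blank correction subtracts, time point by time point, the mean gas volume
of the blank bottles of the same run. Grids must match exactly — blanks
share the schedule, so interpolating them would only hide a configuration
error. Corrected values may be slightly negative early on and are reported
as-is.

## What the simulator emulates

`simulate_bottle()` advances gas evolution on a fine grid (step =
min(reading interval, 0.05 h), which resolves the fast early phase of the
curve) and partitions the evolved gas between the head space and the
fluid:

* head-space over-pressure by the ideal gas law,
  $P = v_{excess} P_{atm} / V_h$;
* a dissolved pool at linear equilibrium, `solubility_coeff` mL of gas per
  kPa of over-pressure (default 0.5 mL/kPa for 60 mL of buffered fluid,
  scaled to 0.25 for the 30-mL manual bottles — dissolution capacity is
  proportional to liquid volume);
* at each vent the head space returns to ambient, a fraction
  `sequestration_frac` (default 0.3) of the then-dissolved gas is
  irreversibly lost — CO₂ consumed by bicarbonate buffering and
  acid–base reactions in the medium — and the remainder re-equilibrates.

This is deliberately the simplest mass-conserving mechanism that makes
recovered gas depend on venting frequency: gas held in solution between
vents is repeatedly taxed at vent time, so sparse venting loses more. The
simulator keeps an exact ledger (produced = vented + residual head space +
dissolved + sequestered, verified to $10^{-9}$ mL at every step), and the
package's tests confirm the two qualitative consequences the mechanism was
chosen for: recovered GP is monotone non-increasing in the venting
interval, and the automated schedule recovers at least the manual
schedule's 48-h GP for every default feed.

Sensor readings pass through a linear response (`gain`, `offset`) with
Gaussian noise whose SD is *proportional to the reading* —
`noise_sd` is the SD in kPa at a 10-kPa reading, default 0.25, i.e. 2.5 %
relative accuracy, matching how pressure-sensor accuracy is specified.
A proportional model matters more than it may seem: with additive noise,
the zero-clamp in `cumulate_pressure()` rectifies pure noise upward on the
~200 near-zero readings of an automated blank, an artifact of tens of
mL/g that would swamp the technique effect being studied. Gauge sensors
cannot read below ambient; recorded values are floored at $-0.5$ kPa.

### Study conditions encoded in the defaults

`default_run_config()` fixes the simulated experiment at the validation
study's design: 2 runs × 6 feeds × 4 replicates per technique, plus 12
blanks per technique. The 12 blanks are split evenly across runs (6 + 6),
since blank correction operates within run; the source protocol does not
state the allocation. The manual serum bottle's fill volume is likewise
unstated; we use 30 mL of fluid in the 60-mL bottle (head space 30 mL),
configurable.

True kinetic parameters per feed ($B$ 230–315 mL/g, $c$ 0.035–0.105 h⁻¹,
$L$ 1.5–4 h) were chosen once so that, *after* CO₂ losses and blank
correction, simulated 48-h GP spans the observed ~115–225 mL/g range with
the observed feed ranking (grains > TMR > silage > hay > straw).
Between-bottle variability uses multiplicative Gaussian effects on $B$: run
CV 2 %, run-by-feed CV 2 %, replicate CV 9 % — the replicate CV set so the
residual SD at 48 h (~17 mL/g) is of the magnitude implied by published
repeatability limits for such systems. Blanks ferment a small absolute
volume (10 mL asymptote, 5 % CV) from residual substrate in the inoculum.

## Calibration and quality checks

Calibration regresses *applied pressure on raw reading* — the direction the
acquisition software needs, since it converts readings to kPa. The bench
protocol is 0, 5, 10, 15, 20 kPa ascending then descending, twice per
sensor (20 records; 720 for a 36-sensor array). Hysteresis is reported (the
largest ascending-vs-descending gap on the kPa scale) but not corrected.
`leak_test()` flags any pressure drop beyond a tolerance (default 1 kPa)
within an overnight window (default 16 h), and `response_check()` compares
a calibrated reading against the ideal-gas expectation
$P_{atm}\,v_{inj}/V_h$ for a known injected volume, flagging drift beyond
the sensor's 2.5 % stated accuracy.

## Repeatability statistics

Endpoint GP values (6, 12, 24, 48 h) are analyzed under the two-way random
model $y = \mu + run + feed + run{:}feed + e$. Components come either from
the balanced expected-mean-squares solution (`anova_ems`) or from REML. For
balanced data REML maximizes the closed-form stratum likelihood of the four
mean squares — when all moment estimates are interior this *equals* the EMS
solution exactly, which is why the two methods agree to numerical identity
on such data; boundary cases are solved by constrained optimization, and
unbalanced data are delegated to `lme4`. Negative moment estimates are
truncated to zero and flagged; the untruncated values are kept as a
diagnostic because they are the unbiased estimator and the right quantity
to average across simulated datasets.

Derived statistics: the repeatability limit $RT = 2\sqrt{2\sigma^2_e}$
(the classical 95 % limit with 1.96 rounded to 2 — the printed source
formula is typographically garbled and this is its standard reading), and
the coefficient of repeatability
$RT\% = 100\,(\sigma^2_R + \sigma^2_F + \sigma^2_{RF}) /
(\sigma^2_R + \sigma^2_F + \sigma^2_{RF} + \sigma^2_e)$. Feed enters
$RT\%$ as a variance component even though it is a fixed factor in the
design — we follow the formula as used in the source field. Note $RT$ is
scale-dependent: a technique that recovers more gas has proportionally
larger absolute residual variation.

## What passing tests do and do not show

The simulator reproduces the *mechanism* of venting-frequency bias, not
bench reality: microbial inhibition by accumulated pressure, pH-dependent
CO₂ chemistry, temperature excursions during manual reading, operator
error of a hand-held gauge, and gas leakage are all absent. Consequently
the simulated automated-vs-manual difference (≈ +10–17 % depending on
endpoint) emerges from dissolution/sequestration alone, and the *absolute*
RT of the manual technique is not elevated by handling error as it is on
real data (its RT% is still lower, as observed). Parameter-recovery and
variance-component results certify the estimators, not any biological
claim.

## Numerical choices and problem sizes

* Simulation step 0.05 h; ledger conservation asserted to $10^{-9}$ mL.
* Threshold venting triggers at the first step where over-pressure reaches
  the threshold (default 4.5 kPa), recording a reading at each vent and at
  the horizon.
* Kinetic fits: tolerance $10^{-8}$, 500 iterations, 3 starts; standard
  errors from the curvature at the solution.
* Monte-Carlo suites are sized to certify the estimators while keeping the
  default test run fast: 200 replicates for kinetic-parameter bias
  (SD 2 mL/g on the 192-point grid), 500 datasets for variance-component
  recovery of $(4, 100, 2, 9)$ under the 2 × 6 × 4 layout, 40 replicates
  per noise level for the bias-vanishes-with-noise property.
* The orchestration tests use a reduced design (3 feeds, 2 replicates,
  4 blanks) purely to exercise structure; the acceptance script runs the
  full 120-bottle experiment.
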