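---
title: "Methods: from chamber traces to population comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chamber traces to population comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoresp)
```

`thermoresp` implements the standard measurement-to-inference chain of
flow-through respirometry for endotherms: calibrated multichannel chamber
traces are reduced to resting oxygen consumption (VO2), carbon dioxide
production (VCO2) and evaporative water loss (EWL); these are converted to
the derived thermal and hygric variables (RER, MHP, MWP, EHL, wet/dry
conductance, RWE, PRWE); and populations are compared with polynomial mixed
models and ANOVA with Student-Newman-Keuls groupings. This vignette explains
the models, the tunable parameters and their defaults, the numerical
decisions, and what the synthetic generator does and does not emulate.

## The measurement model

A trial is one animal resting in a chamber (default 8000 cm^3) flushed with
dried air at a mass-flow-controlled rate (default 3000 ml STPD min^-1,
working range roughly 2.5-4.6 l min^-1). A subsample of excurrent air passes
a humidity probe and is then dried before the O2 and CO2 analysers, so the
measured gas fractions are *dry* fractions and need no water-vapor dilution
correction; the humidity channel alone carries the evaporative signal.
Channels are logged every 10-30 s (default 15 s). Baselines of animal-free
incurrent air are recorded for at least 20 min before and after each trial.

### Calibration

Each gas channel is an affine map fixed by a zero gas (nitrogen) and a span
gas (room air, 20.95% O2, or a precision CO2 mix); the RH probe by two
points (1% over desiccant, 100% saturated); the flowmeter by a
multiplicative STPD factor. `apply_calibration()` is exactly this family of
two-point lines, so applying the identity calibration is a no-op and
calibration commutes with affine re-expressions of the raw readings.

### Baseline drift

Analyser drift is estimated from the two baseline means and interpolated
linearly in time (`fit_baseline()`). Two anchor points admit no higher-order
drift model; the drift line doubles as the time-varying estimate of the
*incurrent* composition, which is what the mass balance needs. Baseline
noise SDs are reported per channel.

### Mass balance

With dry incurrent flow $\dot V_I$ and dry fractions, nitrogen conservation
gives

$$\dot V_{E,dry} = \dot V_I\,\frac{1 - F_iO_2 - F_iCO_2}{1 - F_eO_2 - F_eCO_2},
\qquad
\dot VO_2 = \dot V_I F_iO_2 - \dot V_{E,dry} F_eO_2,
\qquad
\dot VCO_2 = \dot V_{E,dry} F_eCO_2 - \dot V_I F_iCO_2.$$

The algebra is exact (no respiratory-quotient assumption); when RER = 1 the
dry flows coincide. Incurrent reference composition defaults to room air
(FiO2 0.2095, FiCO2 0.0004) but per-timestamp references come from the
baseline drift line, which also absorbs background CO2.

### Evaporative water loss

Excurrent water vapor pressure is relative humidity times the saturation
pressure at the probe temperature, computed with the Magnus form
$P_{sat}(T) = 0.61094\,e^{17.625\,T/(T+243.04)}$ kPa. The constants are
configuration (`magnus_default()`), pinned by the tests, because several
Magnus parameterizations circulate and differ in the third decimal. Vapor
volume flow follows from the dry excurrent flow by partial pressures,
$\dot V_w = \dot V_{E,dry} P_w/(BP - P_w)$, and mass via 18.016 mg mmol^-1
over 22.414 ml mmol^-1. Incurrent air is dried, so after subtracting the RH
baseline all vapor is attributed to the animal. Barometric pressure defaults
to 101.325 kPa with a warning when a trace does not record it.

### The steady-and-minimal window

Resting values are means over a window of at least 20 min in which rates are
steady and minimal. "Steady" is not quantified in common usage, so the
package makes it explicit: a candidate window qualifies when the VO2
coefficient of variation is at most `cv_max` (default 0.10) and the fitted
VO2 slope is at most `slope_max_frac_h` (default 5% of the window mean per
hour); among qualifying windows the minimal-mean-VO2 window wins, near-ties
(1e-9 relative) resolving to the earliest start and then the longest window.
Candidate starts are every sample and candidate lengths everything above the
minimum; the O(n^2) search uses prefix sums and is exact, verified against
an exhaustive brute-force enumeration. If nothing qualifies the minimal-CV
window is returned flagged non-steady. Windows containing non-positive VO2
samples are excluded from candidacy so that baseline-level noise cannot
crash the search; negative instantaneous rates remain visible in the series.

Stability is judged on VO2 only and the VCO2/EWL means inherit the window,
because the three rates must describe one common period.

Before the search the pipeline discards the first `equilibration_tau`
(default 8) chamber time constants $\tau = V/\dot V$ of the animal phase.
During washout the apparent VO2 climbs from zero toward truth, so the
"minimal mean" policy would otherwise deterministically select windows
biased low by the washout tail; after $8\tau$ the residual is
$e^{-8} \approx 3\times10^{-4}$ and the bias is negligible. A related,
smaller effect remains with noisy data: selecting the minimal mean among
many overlapping windows sits slightly below the truth (about 1% at the
default noise), which is inherent to the published "steady and minimal"
rule rather than to this implementation.

## Derived variables

With window means in hand (`assemble_record()`):

* RER = VCO2/VO2; values outside [0.7, 1.0] are preserved but flagged, and
  conversion lookups clamp to the table domain [0.71, 1.00].
* MHP = VO2 x oxycal(RER), MWP = VO2 x hygric(RER), with linear
  interpolation between the conventional knots (19.6-21.1 J ml^-1 and
  0.53-0.67 mg ml^-1 at RER 0.71 and 1.00). The knots are configuration:
  published coefficient tables differ slightly, so the tests pin the
  configured values rather than any one source.
* EHL = 2.4 J mg^-1 x EWL.
* C_wet = (MHP/m)/(Tb - Ta) and C_dry = ((MHP - EHL)/m)/(Tb - Ta), in
  J g^-1 h^-1 degC^-1. The formula is whole-animal but the customary units
  are mass-specific, so the package divides by mass: units win. Below a
  body-air gradient of `gradient_floor_C` (default 0.5 degC) the ratio is
  numerically meaningless and the values are returned NA with a flag; above
  thermoneutrality C_dry can legitimately be negative (EHL > MHP) and is
  reported as such.
* RWE = MWP/EWL; the point of relative water economy (PRWE) is the Ta where
  the fitted RWE curve crosses 1. Higher PRWE means metabolic water covers
  evaporative losses over a wider, warmer range.
* Mass-independent values divide by mass^b with marsupial exponents
  MR 0.74, EWL 0.68, C_wet 0.57 by default. Some reports print
  metabolic-rate units on g^-0.75 while stating 0.74 in their methods; the
  registry keeps 0.74 and both are configurable
  (`scaling_exponents()`). Body mass is the mean of the pre- and post-trial
  weighings; Tb is the single post-trial cloacal measurement paired with the
  whole window, mirroring how such trials are actually instrumented.

## Statistical models

### Thermal responses

Each variable's response to Ta is fitted per population as a linear mixed
model with a quadratic fixed polynomial and a random intercept per
individual, by REML (`fit_thermal_response()`, lme4). Ta is centered and
scaled to unit SD before polynomial expansion — raw-scale quadratic
coefficients are tiny and the coded scale keeps the optimizer and the
reported coefficients well conditioned. The coding descriptor is stored with
the fit and all predictions are made on the raw Ta scale, so no result
depends on the coding (a property the tests verify by refitting under raw
coding). Singular fits (zero individual variance) are returned with a
`boundary` flag rather than an error.

### Tests of effects

The individual random effect is tested by a likelihood ratio between the ML
fits with and without the random intercept. The variance sits on the
boundary of its parameter space under the null, so the reference
distribution is the 50:50 mixture of $\chi^2_0$ and $\chi^2_1$; a statistic
of zero gets p = 1.

Between locations, `compare_locations()` fits the joint model
`y ~ (Ta + Ta^2) * population + (1 | individual)` and reports large-sample
Wald chi-squared tests for the population main effect and the
Ta-by-population interaction, plus per-population Wald z contrasts against a
declared reference population (evaluated at the Ta center). Small-sample
denominator-df corrections (Satterthwaite, Kenward-Roger) are deliberately
not reimplemented; the large-sample reference is adequate once the number
of individuals is not tiny, and the package's own calibration suite sizes
its null simulations (12 individuals per population) accordingly. With few
individuals the main-effect test — a between-individual contrast — is
expected to be somewhat anticonservative; users with small cohorts should
read main-effect p-values with that in mind.

### PRWE estimation

`estimate_prwe()` fits the quadratic mixed model to RWE, converts the coded
coefficients to a raw-scale quadratic, takes its analytic roots, refines
each by bisection on the fitted curve, and returns the root nearest the
measured Ta range. Roots more than 5 degC outside the range are flagged as
extrapolations; a curve identically 1 is flagged degenerate; no real root
yields NA with a `no_root` status. With two real roots the one nearest the
data wins, which matches the physiological reading (RWE declines with
warming, and the far root of a shallow quadratic is an artifact of the
polynomial).

### Standard values and SNK

Standard ("basal") records are trials with Ta within
`thermoneutral_ta_C +/- thermoneutral_window_C` (default 26 +/- 1 degC).
`anova_snk()` runs a one-way ANOVA and groups ordered means by the stepwise
Student-Newman-Keuls procedure: the full range of k means is tested against
`qtukey(1 - alpha, k, df)`, significant stretches are split into their two
subranges, and stretches inside an accepted stretch are not tested. Unequal
group sizes use the harmonic mean n, the standard SNK extension. Letters are
the maximal homogeneous stretches, so groups sharing a letter are not
significantly different at alpha. Under a complete null the first step is an
exact alpha-level studentized-range test, so a single shared letter appears
in exactly 1 - alpha of replicate experiments — no more.

## The synthetic generator

`endotherm_scenario()` encodes a Scholander-Irving resting curve: below the
thermoneutral zone, metabolic heat follows the conductance line
MHP = C_wet (Tb - Ta), extrapolating to zero at Tb; within the TNZ, VO2 is
BMR; above it, VO2 rises linearly (default 4% of BMR per degC) while Tb
drifts upward and EWL rises exponentially (defaults 0.15-0.26 per degC
across presets). The closure identity — conductance-line MHP at the TNZ
lower bound equals BMR-derived MHP — means BMR, Tb and the TNZ bound fully
determine C_wet, so the generator derives conductance per individual rather
than treating it as a free dial; supplying C_wet instead derives the TNZ
bound from the same identity. Individuals get lognormal BMR and EWL
multipliers (SD 0.06 and 0.08) and Gaussian Tb offsets (SD 0.3 degC).

`simulate_trace()` forward-models the chamber: steady-state excurrent
fractions from the inverse mass balance, first-order washout
$F(t+\Delta) = F_{ss} + (F(t) - F_{ss})e^{-\Delta\,\dot V/V}$ (the discrete
update equals the continuous solution at sample times to machine precision),
a psychrometric vapor channel riding on a 1% residual background humidity,
baselines modelled as instantaneous bypass readings of incurrent air, then
per-channel linear drift and Gaussian analyzer noise. Noise defaults
(O2 1.5e-4, CO2 1.0e-4 as fractions, RH 0.5%) give a per-sample VO2
coefficient of variation near 5% for a resting animal at the default flow —
comfortably inside the window stability bounds while leaving window means
reproducible to well under 1%.

Default trials are 3 h of animal phase with 20-min baselines at 15-s
sampling; the steady-state-plus-washout structure makes longer traces
redundant for a resting window, and every duration is configurable. The
default cohort is 4 populations x 6 individuals x 8 Ta levels (6-34 degC) =
192 traces. The four presets (arid, mesic-cool, montane, tropical) are
round-number archetypes spanning realistic contrasts in BMR, EWL, Tb and
heat response; they are illustrative, not estimates for any real population.

What the generator does *not* emulate: activity bouts and torpor, circadian
Tb rhythms, behavioral thermoregulation, chamber temperature gradients, and
irregular measurement grids (available only via the `dropout` option).
Passing recovery tests on this generator therefore demonstrates that the
inference chain is unbiased for a resting steady-state animal under
first-order mixing and linear drift — not that it is robust to every
artifact of live-animal data.

## Numerical choices and degenerate inputs

* Window near-ties resolve at 1e-9 relative tolerance (earliest start, then
  longest window); a constant series returns the whole phase.
* PRWE roots are bisected to 1e-10 degC after the analytic solve.
* `compute_gas_exchange()` rejects Fe sums >= 1 and non-positive flow;
  negative computed VO2 is returned (and excluded from window candidacy)
  rather than silently clipped, because it diagnoses baseline or
  calibration faults.
* `compute_ewl()` rejects vapor pressures at or above barometric pressure.
* Missing Tb yields records with conductance fields NA and a flag; missing
  barometric pressure defaults to 101.325 kPa with a warning.
* Zero within-group variance makes SNK undefined and is an error; zero
  between-individual variance is a flagged boundary fit, not an error.

## Problem sizes used by the validation suite

The packaged checks run at sizes a laptop handles in minutes: 10,000 random
truths for the mass-balance inversion; the full 192-trace default cohort for
end-to-end recovery (population-mean BMR and basal EWL within 3% of
generative truth); 200 replicate cohorts for PRWE recovery under a linear
RWE truth and for the null calibration of the location tests (KS uniformity
of p-values, LRT rejection at or below the boundary-mixture nominal rate,
SNK single-letter rate at its exact 95% expectation); and 100 random series
against the exhaustive window-search oracle.

## Known limitations

* Large-sample Wald references, not small-sample df approximations (above).
* The quadratic thermal response is a description, not a mechanistic model;
  PRWE from a quadratic RWE fit inherits its extrapolation behavior, which
  is why extrapolated roots are flagged.
* The "minimal mean" window rule has a small downward selection bias at
  high analyzer noise (documented above), bounded by the noise level.
* Conversion coefficients and Magnus constants are conventions; results are
  only comparable across studies that use the same tables, which is why they
  are explicit configuration here.
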