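---
title: "Methods: gadoxetate tracer kinetics and reproducibility statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gadoxetate tracer kinetics and reproducibility statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverDCE)
```

## What the package models

Gadoxetate is a liver-specific gadolinium contrast agent: after an
intravenous bolus it distributes in the extracellular space, is actively
taken up into hepatocytes by OATP transporters and excreted into bile by
MRP2. Inhibition of either step — by a drug, or by drug-induced liver
injury — changes the liver enhancement pattern in dynamic
contrast-enhanced (DCE) MRI. The package turns ROI signal-time curves from
a spoiled gradient-echo dynamic acquisition into two rate constants per
subject and scan day:

* `Ktrans` (mL/min/mL): hepatocellular uptake — the hepatic plasma
  clearance of gadoxetate per unit liver volume, referred to whole-blood
  concentration;
* `kbh` (mL/min/mL): biliary efflux from the hepatocyte compartment.

The forward model is a chain of four stages, each exposed as a function so
every stage can be validated independently.

### 1. Blood input function (`inputFunction`)

A measured arterial input is impractical in small rodents at these frame
rates, so the blood curve is model-based. The default registry entry,
`"wholebody-1c"`, infuses the weight-normalised dose (25 µmol/kg) at a
constant rate over the injection window into a single whole-body
extracellular distribution volume with first-order elimination:

$$\frac{dA}{dt} = R(t) - k_{el} A, \qquad c_b = A / V_d .$$

This is the simplest model consistent with weight-normalised dosing and
whole-body clearance; its closed form is exact, and the registry
(`registerAifModel`) accepts alternative published forms without touching
any caller. Defaults (all in the study configuration): distribution volume
250 mL/kg — the extracellular water space of the rat, giving a peak blood
concentration of about 0.1 mM at the standard dose — and elimination rate
0.04 min⁻¹, i.e. a whole-body half-life of roughly 17 min, the order
observed for gadoxetate in rats with combined renal and biliary clearance.
Injection defaults: start at the end of the baseline window, 10 s
duration.

### 2. Liver compartment (`hepatocyteConcentration`)

The hepatocellular concentration per unit liver volume obeys the linear
uptake–efflux compartment
$$\frac{dC_h}{dt} = K^{trans} c_b(t) - k_{bh} C_h(t), \quad C_h(0)=0,$$
equivalently an exponential convolution of the input. The solver advances
the exact solution for a piecewise-linear input over each frame interval
(per-step recursion with `E = exp(-k_{bh}\,\Delta t)` and analytic
integrals of the linear segment), switching to a series expansion when
`kbh * dt < 1e-8` so the `kbh -> 0` limit is smooth. The scheme is
unconditionally stable and exact for the interpolated input; the only
discretisation error is the second-order interpolation of `c_b` between
frames, which the test suite verifies converges at `O(dt^2)` and is below
`1e-6` relative at 1 s sampling. Rates are per minute internally; the
public time axes are seconds, converted only at module boundaries (a
units-audit property test guards this).

### 3. Relaxation (`r1Timecourse`)

Extracellular and hepatocellular gadoxetate relax water at different
rates, because the intracellular pool is partially protein-bound. The R1
model is linear with two relaxivities:
$$R_1(t) = R_{1,0} + r_e\, v_e c_b(t) + r_h\, C_h(t).$$
`v_e` is the extracellular volume fraction of liver tissue (default 0.23,
a typical rat liver extracellular water fraction); it is held fixed by
default and can be co-fitted (`fitOptions(fitVe = TRUE)`). Baseline R1 and
the relaxivities are configuration entries keyed by field strength, not
constants in code; the packaged defaults (4.7 T: R1 1.00 s⁻¹, r_e 6.7,
r_h 9.8 mM⁻¹s⁻¹; 7 T: 0.75, 6.2, 8.4) are literature-style values chosen
once for the synthetic studies and should be replaced by each study's own
calibrated constants.

### 4. Signal (`spgrSignal`)

The RF-spoiled gradient-echo steady state,
$$S = s \sin\alpha \frac{1-E}{1-E\cos\alpha}, \quad E = e^{-TR\,R_1},$$
with the flip angle taken per centre from the configuration (20° or 30°)
and TR = 5.8 ms. T2* decay is not modelled: at TE = 1.1 ms its weighting
is negligible, and the assay model is T1-based; TE is carried as metadata
only. The arbitrary-unit scale `s` is anchored so the model at baseline R1
equals the mean of the pre-contrast frames (default 10), which makes all
estimates invariant to rescaling the curve; co-fitting the scale is
available as an option but couples it with `v_e` and is off by default.

## Fitting and quality control

`fitCurve` minimises the sum of squared residuals in *signal* space —
fitting the full chain rather than inverting noisy signals to
concentration, which would distort the noise — with bounded
Levenberg–Marquardt (minpack.lm), start values `Ktrans = 0.5`,
`kbh = 0.1` mL/min/mL (mid-range of reported rat values), bounds `[0, 5]`
and `[0, 2]` bracketing all plausible values with margin, and cost
tolerance `1e-10`. The fit is deterministic: no random restarts.

Visual artefact rejection is replaced by explicit, configurable QC flags:
`baseline-missing` (too few pre-contrast frames or a degenerate all-zero
baseline), `low-enhancement` (peak enhancement below 5% of baseline),
`non-convergence`, and `bound-hit` (a rate pinned to its box bound). Any
flag marks the row excluded; `fitCohort` keeps excluded rows in the table
so exclusion accounting stays visible, and every statistic ignores them.

## Reproducibility statistics

All definitions use the fixed 1.96 normal-theory multiplier (no
small-sample t correction — the definitions fix the constant):

* **Reference value**: mean over substudy baseline means, ±1.96 SE. Each
  substudy contributes one mean per biomarker; substudies, not subjects,
  are the unit of reproducibility.
* **Reproducibility**: 1.96 SD over substudy means, % of mean (a 95%
  tolerance interval, TI).
* **Repeatability**: per saline-saline substudy, the TI over the two day
  means (subjects are pooled into a day mean first — a substudy returns
  one value per day — so identical days give exactly 0%); the alternative
  `"differences"` method uses the within-subject SD of paired day
  differences, `sd(d)/sqrt(2)`. Cohort repeatability is the mean over
  substudies with its CI; substudies with fewer than two complete pairs
  are dropped.
* **Effect size**: per substudy with an inhibitor arm,
  `100 (mean_saline − mean_inhibited)/mean_saline` using the same
  subjects' day-1 saline and day-2 inhibitor values; aggregated as mean
  ± CI over substudies.
* **Absolute detection limit**: smallest inhibition `d` whose TI (set by
  the saline reproducibility) no longer overlaps the benchmark CI;
  `(1-d)(1+TI) = 1-CI` gives `d = 1-(1-CI)/(1+TI)`. A property test
  checks the closed form against bisection.
* **Relative detection limit**: `sqrt(2)` × repeatability — the
  repeatability coefficient, the least significant change between two
  paired measurements.
* **Variance partition**: two-way mixed ANOVA (day within subject,
  substudy between; `stats::aov` with an `Error(subject)` stratum) on
  saline-saline repeat data, sums of squares reported as percentages of
  the total in four components: between-substudy, between-subject,
  between-day, and "other" = interaction + residual, so the four sum to
  100%. The fixture expectations in the tests were frozen from an
  independent mixed-design ANOVA implementation.
* **Group comparison**: one-way ANOVA per stratification label plus
  unpaired pairwise t-tests without pooled SD and without multiplicity
  adjustment — these comparisons are exploratory by design. Degenerate
  input (all groups constant and equal) is reported as such rather than
  as a number.

## The synthetic cohort

`cohortDesign`/`simulateCohort` generate the statistical structure the
analysis assumes: substudies (centre × field), subjects nested in
substudies, two days per subject, with independent mean-one log-normal
multipliers at each level. Log-normal (not additive normal) variation
keeps rates positive at large CVs, and the parameterisation
`sdlog = sqrt(log(1+cv^2))` makes each factor's coefficient of variation
exactly the design value. Defaults are the package's reference study
conditions: 3 substudies × 4 subjects per arm × 2 days, saline-saline and
saline-rifampicin arms, CVs of 20% (substudy), 15% (subject), 3% (day),
day-2 rifampicin multipliers 0.25 on `Ktrans` and 0.33 on `kbh` (75% and
67% inhibition), population means 0.90 and 0.19 mL/min/mL. Curves are
rendered on a 5 s grid, 10 baseline frames, 30 min duration, with additive
Gaussian magnitude noise of 3% of baseline (the high-SNR volume-coil
regime; Rician noise is available by flag). One master seed drives
separate substreams for parameter draws and noise, so a parameter table
can be re-rendered at other noise levels.

What the generator does *not* emulate: respiratory-gating artefacts, ROI
placement variability, B1/flip-angle miscalibration, inflow effects,
drift, or real relaxivity miscalibration between centres. Passing
recovery tests therefore demonstrates correctness of the estimation chain
under the model's own assumptions, not robustness to everything real data
can do.

## Validation surface and problem sizes

The test suite validates each stage against an independent route:
high-precision closed-form values for the signal equation; stiff ODE
solves (deSolve) for the input function and the liver compartment (100
random parameter draws, `1e-5` relative); hand-computed and independently
frozen values for every statistic; a frozen mixed-ANOVA fixture for the
variance partition; and a 1000-replicate null simulation showing the
one-way ANOVA holds its nominal 5% type-I error. End-to-end, a designed
cohort at the reference conditions returns its effect sizes within ±5
points and a between-day variance component that is the smallest of the
four (and below 1% when the day CV is zero). Noise-recovery checks use 50
replicates at 3% noise; cohort-level checks use the 3 × 4 × 2 default
design — sizes chosen to make Monte-Carlo error small relative to the
tolerances being asserted.

## Known limitations

* The input function is a one-compartment whole-body model; a published
  two-phase form can be registered but is not the default.
* `v_e` and the signal scale are fixed/anchored by default; co-fitting is
  available but increases parameter coupling.
* Relaxivity and baseline-R1 defaults are literature-style, not
  study-calibrated; absolute rate estimates shift with these constants,
  which is precisely the between-centre sensitivity the reproducibility
  statistics are designed to expose.
* The QC policy is an explicit operationalisation of what is usually a
  visual call; its thresholds (5% enhancement) are configurable, not
  canonical.
* No uncertainty is attached to the reproducibility statistics themselves
  ("error on the error"): that would require substantially larger
  cohorts.
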