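# liverDCE

Quantitative analysis of gadoxetate dynamic contrast-enhanced (DCE) MRI of
the rat liver, for imaging scientists and DMPK groups who use hepatobiliary
transporter function as an early safety biomarker for drug-induced liver
injury (DILI) and drug–drug interactions (DDI). The package estimates the
hepatocellular uptake rate *K*<sup>trans</sup> and the biliary excretion
rate *k*<sub>bh</sub> (both in mL/min/mL of liver) from ROI signal-time
curves, and quantifies how trustworthy those estimates are across centres,
scanners and scan days.

## The model

Gadoxetate is taken up by hepatocytes (OATP transporters) and excreted into
bile (MRP2), so its liver kinetics follow a linear two-compartment
uptake–efflux model driven by the blood concentration *c*<sub>b</sub>(*t*):

  d*C*<sub>h</sub>/d*t* = *K*<sup>trans</sup> *c*<sub>b</sub>(*t*) −
  *k*<sub>bh</sub> *C*<sub>h</sub>(*t*),  *C*<sub>h</sub>(0) = 0,

solved by exact exponential convolution on a piecewise-linear input.
*c*<sub>b</sub>(*t*) comes from a model-based input function (default: a
constant-rate bolus infused into one whole-body extracellular volume with
first-order elimination; other models plug into a registry). The liver R1
time-course uses compartment-specific relaxivities,

  *R*<sub>1</sub>(*t*) = *R*<sub>1,0</sub> + *r*<sub>e</sub> *v*<sub>e</sub>
  *c*<sub>b</sub>(*t*) + *r*<sub>h</sub> *C*<sub>h</sub>(*t*),

and maps to the measured signal through the spoiled gradient-echo (FLASH)
steady-state equation *S* = *s* sin α (1−*E*)/(1−*E* cos α),
*E* = e<sup>−TR·R1</sup>. Rates are estimated per subject-day by bounded
Levenberg–Marquardt least squares in signal space, with explicit quality
control (low enhancement, non-convergence, bound hits) replacing visual
artefact rejection.

On top of the fits sits the reproducibility framework: reference values
with 95% confidence intervals (1.96 × SE), between-substudy reproducibility
and within-subject repeatability as 95% tolerance intervals (1.96 × SD, %
of mean), absolute and relative detection limits for an inhibition effect,
rifampicin effect sizes, a two-way mixed-ANOVA variance partition
(between-substudy / between-subject / between-day / other), and stratified
one-way ANOVAs. A hierarchical synthetic-cohort generator with known ground
truth exercises the whole chain.

## Worked example

Simulate a three-substudy cohort (saline-saline repeat arm plus
saline-rifampicin arm, 4 rats per arm, 3% signal noise), fit every curve,
and build the reproducibility report:

```r
library(liverDCE)

des <- cohortDesign(seed = 21)      # defaults: CVs 20/15/3%, 75%/67% inhibition
sim <- simulateCohort(des)          # curves + ground truth
tab <- fitCohort(sim$curves)        # one row per subject-day, QC-flagged
rep <- reproReport(tab)
rep
```

```
ReproReport over biomarkers: Ktrans, kbh 
  Ktrans: reference 0.74 +/- 0.12 mL/min/mL (n = 3 substudies)
    reproducibility 28%; repeatability 3%
    detection limits: absolute 34%, relative 5%
    inhibitor effect size 75 +/- 0%
    variance components: between_substudy 71.8%, between_subject 27.4%, between_day 0.0%, other 0.7% 
  kbh: reference 0.19 +/- 0.02 mL/min/mL (n = 3 substudies)
    reproducibility 19%; repeatability 3%
    detection limits: absolute 25%, relative 4%
    inhibitor effect size 67 +/- 1%
    variance components: between_substudy 36.1%, between_subject 59.9%, between_day 0.6%, other 3.4% 
```

Reading this: the reference value is the mean of the substudy baseline
means with its 95% CI; reproducibility is the tolerance interval across
substudies (how far a single new substudy mean may scatter);
the absolute detection limit is the smallest inhibition distinguishable
from that scatter in a single measurement, while the relative detection
limit (√2 × repeatability, the repeatability coefficient) applies to
paired baseline/follow-up designs. The simulated rifampicin effect
(Ktrans × 0.25, kbh × 0.33) is recovered as 75% and 67% inhibition, well
above both limits — the situation the assay is designed for. The between-day
variance component is the smallest, as designed (day CV 3% versus 15%
between subject and 20% between substudy).

Curves, cohort tables and reports read/write plain CSV/JSON
(`readCurves()`, `writeCohortTable()`, `writeReport()`); acquisition and
relaxation constants per centre and field strength live in a YAML study
configuration (`defaultStudyConfig()`). A thin CLI over the same functions
is in `inst/scripts/assay.R` (`simulate`, `fit`, `stats`,
`detect-limits`).

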