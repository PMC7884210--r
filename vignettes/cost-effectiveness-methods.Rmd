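---
title: "Methods: trial-based cost-effectiveness of an enhanced recovery program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness of an enhanced recovery program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(erpcea)
library(dplyr)
```

`erpcea` implements the full analysis chain of a trial-alongside economic
evaluation of an enhanced recovery program (ERP) versus standard
perioperative care for open liver resection: patient-level micro-costing,
EQ-5D quality-of-life analysis, long-term survival comparison, and a
decision-analytic model projecting costs and QALYs with probabilistic
sensitivity analysis. This vignette describes the models, their
assumptions, the tunable parameters, and the design decisions that were
genuinely open.

## The evaluation problem

An ERP bundles perioperative interventions — preoperative education,
carbohydrate loading, oral nutritional supplements, goal-directed fluid
therapy guided by cardiac-output monitoring, early mobilization,
intensified physiotherapy — that shorten hospital stay and reduce
complications after major surgery. The economic question is whether the
bundle's own costs are offset by shorter stays and lower downstream
resource use, and whether any quality-of-life or survival advantage makes
it cost-effective at conventional willingness-to-pay thresholds
(£20,000–£30,000/QALY in the NHS). The package takes the NHS perspective:
hospital and community health-care costs are counted; productivity losses
and informal-caregiver time are recorded but not monetized.

## Micro-costing

Each patient's resource use is costed with fully absorbed unit rates
(`unit_cost_schedule()`; GBP):

| component | rate | unit |
|---|---|---|
| anaesthetic time | 9.16 | per minute |
| theatre time | 15.70 | per minute |
| intensive care bed | 1652.80 | per day |
| high dependency bed | 502.08 | per day |
| ward bed | 151.68 | per day |
| carbohydrate drink (ERP only) | 8.40 | per patient |
| nutritional supplement (ERP only) | 0.14 | per bottle |
| cardiac-output monitoring (ERP only) | 91.20 | per patient |

Daily hospital costs are assumed linear — the first day costs the same
as every later day — which is the conventional simplification for
fully absorbed rates; the `outlier_sensitivity()` helper supports the
standard robustness check of excluding extreme prolonged-stay patients.
Readmission days are costed at the ward rate unless a care level is
recorded. Community unit rates (GP surgery and home visits, practice and
district nursing, outpatient clinics, emergency attendances) are
configuration with round-figure defaults in the spirit of the national
community-costing compendia; help from friends and family is costed at
zero under the NHS perspective. Group summaries use type-7 quartiles
(R's default linear interpolation between order statistics); printed
currency is rounded to the pound, halves away from zero, while internal
arithmetic is exact.

## Quality of life

EQ-5D-3L states observed at days 0 (preoperative baseline), 2, 3, 5, 7,
10, 14 and 28 are scored with the UK time-trade-off tariff in
additive-decrement form (constant term 0.081, per-dimension level-2/3
decrements, N3 term 0.269; minimum −0.594). The tariff is configuration
(`value_set()`, `read_value_set()`) so other national tariffs can be
substituted.

The 28-day summary is the trapezoidal area under the utility curve
(utility-days). Three conventions are fixed here because the endpoints
dominate the integral: the integration window is day 0 through day 28
(starting at the preoperative baseline rather than at surgery — the
choice is configurable simply by passing a trajectory that starts where
you prefer); missing day-0 or day-28 observations are an error, never
extrapolated, while missing interior days are linearly interpolated
(which the trapezoid rule does implicitly); and patients who die within
the window carry utility 0 from death onward, the standard QALY
convention. A between-arm AUC difference is annualized by dividing by
365 days/year and reported to 3 decimal places; this convention turns
the motivating trial's printed median AUCs (37.2 vs 35.6) into its
printed 0.004 QALY gain. Note that AUC *levels* of that size exceed the
mathematical bound of 28 × max-utility for a 28-day window under any
EQ-5D tariff, so only the AUC *difference* is treated as meaningful
arithmetic; the synthetic generator targets the ~1.6 utility-day arm
shift, not the printed levels. Arms are compared with a two-sided
Mann-Whitney U test.

## Survival

With every patient traced to 5 years there is no censoring, so survival
at a fixed horizon is a simple alive count and Kaplan-Meier curves equal
the empirical survival functions (ties between an event and a censoring
time follow the standard at-risk convention). Horizon comparisons use a
2×2 test chosen by sample size: Fisher's exact test (two-sided,
probability-mass criterion) when any observed or expected cell is below
5, otherwise Pearson's chi-square without continuity correction. The
classic small-sample rule looks only at expected counts, but that
assigns chi-square to the 2-year table of the motivating trial
([[42, 4], [33, 12]], minimum expected count 7.9) whereas the trial used
Fisher there; extending the rule to observed cells reproduces the
trial's test assignment at every horizon and subgroup, and the Yates
flag is exposed for users who prefer the corrected chi-square.

## The decision model

`markov_spec()` defines a decision tree feeding a three-state annual
Markov cohort: at discharge each arm's cohort is split over
*alive without complications*, *alive with complications* and *dead*
using the arm's in-hospital mortality and discharge-complication
probability; thereafter survivors can develop a complication, resolve
one, remain in state, or die.

Annual death probabilities are arm-specific for cycles 1–5, derived from
the trial's observed 1-, 2- and 5-year survival fractions (the 2–5 year
interval is interpolated at a constant hazard); from cycle 6 they come
from a background life table multiplied by a relative risk (default 2)
for survivors of high-risk surgery. The bundled life table
(`uk_life_table()`) is a synthetic Gompertz approximation to recent UK
period mortality; `read_life_table()` accepts a real table as CSV.

Key defaults, all overridable per arm:

* horizon 10 years — the model's stated projection window (a 15-year
  variant is one argument away);
* discount rate 3%/year for both costs and effects (NICE reference
  case);
* cycle credit at end of cycle, with a `half_cycle` flag for
  trapezoidal (half-cycle-corrected) credit;
* state utilities 0.80 (no complications) / 0.60 (complications) and
  annual follow-up costs £250 / £1,500 — literature-style configuration
  values, not trial measurements;
* one-off in-hospital cost per arm equal to the trial's mean hospital
  plus community cost per patient;
* a cycle-0 QALY bonus of 0.004 for the ERP arm, carrying the 28-day
  quality-of-life gain into the model additively (set it to 0 to drop
  this).

Discounted life-years, QALYs (occupancy × utility) and costs accumulate
per cycle; `icer()` forms the incremental comparison with dominance
labelling. The engine enforces occupancy conservation to 1e−12 every
cycle and is verified against closed forms (constant-hazard life
expectancy is a geometric series; an immortal full-health undiscounted
cohort returns exactly the horizon).

A worked-table caveat: published three-column CE summaries of the
motivating trial print costs 9538.30/14793.10 and effects 6.9/6.1 with
an ICER of −6748.30/QALY, but the arithmetic of those four inputs gives
−6568.50/QALY — the published effect difference was evidently not
exactly 0.8 QALYs. The package documents both numbers and asserts
neither; its own base case is computed from its own calibrated inputs.

## Probabilistic sensitivity analysis

`psa_config()` assigns each varied parameter a distribution centred on
its base-case value: beta for probabilities and utilities
(mean/effective-sample-size parameterization, default ESS 100), gamma
for costs (mean/CV, default CV 0.2, in-hospital costs 0.1) and for the
survivor relative risk (CV 0.15). The varied set covers the discharge
and transition probabilities, state utilities, per-state annual costs,
in-hospital costs and the relative risk; which parameters a published
analysis varied is rarely stated, so the set is configuration. Each
parameter draws from its own RNG stream seeded by (master seed,
parameter id), so adding a parameter never perturbs the other
parameters' draws — a property the regression tests rely on. Draws that
would produce an invalid model are resampled from a dedicated follow-up
stream and counted (with beta/gamma families this is essentially
unreachable).

Each of the 10,000 default iterations reruns both arms and records the
incremental cost/effect pair. `ceac()` converts the cloud into a
cost-effectiveness acceptability curve over a £0–£50,000/QALY grid
(fraction of draws with positive net monetary benefit λΔE − ΔC);
`interval_95()` gives percentile intervals for ΔC and ΔE plus a
quadrant-aware ICER summary, since ratio confidence intervals are
unstable when a cloud straddles quadrants.

## The synthetic trial generator

No patient-level data from the motivating trial were deposited, so
`generate_trial()` draws datasets with the structure the analysis
assumes: 46 ERP / 45 standard patients; log-normal theatre times and
lengths of stay matched to the trial's printed medians and IQRs (stays
on a half-day grid, since ICU stays are recorded in half days); Poisson
community-usage counts matched to the printed totals (per-patient
variance was never reported, so Poisson is the minimal choice);
latent-utility EQ-5D trajectories — baseline ≈0.85, post-operative
trough at day 2, exponential recovery, arm-specific depth/speed chosen
to give the ≈1.6 utility-day AUC advantage — snapped to the nearest
state on a representative EQ-5D-3L ladder; and survival from a
piecewise-constant hazard on [0,1), [1,2), [2,5) years that reproduces
the trial's survival fractions in expectation, with no censoring before
5 years (alive means exactly 5.0). The generator is deterministic given
a seed.

What it deliberately does not emulate: the randomization imbalance in
P-POSSUM scores and diagnosis mix as a *confounder* (diagnosis
frequencies are matched, but outcomes are drawn independently of them),
correlation between length of stay and subsequent community use, or
heavy-tailed cost outliers like the two prolonged-stay patients of the
motivating trial. Passing tests on synthetic data therefore demonstrate
correctness of the arithmetic and the statistical machinery, not
robustness to real-data pathologies; the outlier-exclusion sensitivity
analysis exists precisely because real cost data are uglier than these
draws.

## Numerical choices and testing scale

Exact checks use 1e−12 (occupancy conservation) or closed-form equality;
Monte Carlo checks use explicit standard-error bounds (3 SE across the
18 simultaneous survival-fraction checks, keeping the family-wise
chance-failure rate under 1%). The default test suite generates trials
of up to 3,000 patients per arm for convergence checks and runs PSA
clouds of 300–10,000 iterations; the full pipeline example below uses
1,000 iterations, which resolves CEAC probabilities to about ±1.5
percentage points.

```{r pipeline, eval = FALSE}
out <- tempfile("erpcea-run-")
run_pipeline(out, seed = 1, n_iterations = 1000, figures = TRUE)
list.files(out)
```

## Known limitations

* State utilities, follow-up costs and the survivor relative risk are
  configuration defaults, not estimates from the trial; absolute model
  outputs (expected costs, QALYs, the ICER) move with them, though the
  qualitative ERP-dominance finding is robust across the PSA cloud.
* The cohort is a single representative age/sex profile; no
  microsimulation or patient-level heterogeneity in the projection.
* No inflation adjustment between the 2011 cost year of the community
  rates and later tariff years; no societal costing.
* The bundled life table is a smooth synthetic approximation; users
  wanting registry-grade life expectancy should supply a national table.
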