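---
title: "An individual-level microsimulation of HIV treatment sequencing and its cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-level microsimulation of HIV treatment sequencing and its cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hivcea` simulates treatment-experienced, integrase-inhibitor (INI)-naive
HIV patients one at a time through monthly cycles, from entry at
virological failure until death or age 100, and accrues discounted costs
(EUR, collective-perspective direct costs only) and quality-adjusted life
years. Two strategies are compared on the same simulated cohort: first-line
dolutegravir (DTG) or raltegravir (RAL), each combined with an optimized
background therapy (OBT), followed by a fixed sequencing algorithm.

Each patient carries tracked variables: age, sex, CD4 count, virologic
suppression status, current treatment line, INI-resistance status, active
opportunistic infection (OI) and OI history. Each month, in a fixed order,
the engine evaluates: (1) death (HIV-attributable excess by CD4 stratum,
tested before background mortality from an abridged life table; the HIV
component is multiplied by an acute factor during active-OI months),
(2) OI resolution and onset (at most one active episode; five types tried
in a fixed order), (3) virologic evaluation — a week-48 response Bernoulli
resolved at month 12 on a line, then a constant monthly late-failure
(rebound) probability for months 12–23 and a higher one from month 24,
(4) adverse-event discontinuation, (5) line transition, (6) CD4 update,
and (7) cost/QALY accrual. The order is frozen and verified by a scripted
trajectory test whose accruals are recomputed by hand.

### Treatment lines and resistance

Line 1 is DTG+OBT1 or RAL+OBT1. At a *virologic* failure of line 1 (only
there), the patient may acquire INI resistance with an arm-specific
probability; the flag is permanent and selects the rest of the sequence:

* no resistance: DTG+OBT2.0 (DTG arm) or OBT2.1 (RAL arm), then
  Salvage 1, then Salvage 2 — four lines in all;
* INI resistance: OBT2.2 then Salvage 2 — three lines.

Adverse-event discontinuations trigger the same successor logic but never
confer resistance (resistance requires replication under drug pressure).
After failing the final salvage line the patient stays on that regimen,
continues to accrue its cost, and is flagged as failing the last line;
from then on CD4 declines linearly (the terminal-decline scenarios below).

Week-48 suppression rates (with their confidence intervals used in the
sensitivity analysis) are 70.9% / 63.7% on line 1 (DTG / RAL), 60.6% or
50.8% on line 2 (without / with INI resistance) and 10% / 7% on the two
salvage lines; monthly late failure is 0.76% (lines 1–2) or 0.88%
(salvage) in months 12–23 and 2.75% thereafter, the printed rates being
used as-is. The "thereafter" rate is extended unchanged beyond week 240,
the simplest constant reading.

### CD4 dynamics

While suppressed, a patient gains the line's annual week-48 CD4 increase
(190 / 189 cells/µL on line 1, 176 on line 2, 118 on salvage) with a
front-loaded schedule: two thirds of the annual gain in months 1–2, the
remaining third spread uniformly over months 3–11 (so months 1–11 sum
exactly to the annual figure), then 14 cells/year in months 12–23 and 19
cells/year later (0 on salvage lines). CD4 is capped at 1,000 cells/µL.
On any line after the first, the cumulative gain is capped at the total
gain the patient actually realized on line 1 — the per-patient reading of
the rule that later lines cannot outperform the first; a patient who never
responded on line 1 therefore regains nothing later. While failing
therapy before the last line, CD4 plateaus (no gain, no decline); gain is
specified only under maintained suppression, decline only after the last
line.

### Costs, utilities, discounting

Monthly ART costs by component: DTG or RAL 612, OBT1 986, OBT2.0 1,698,
OBT2.1 2,218, OBT2.2/salvage 2,491 (weighted means, with min/max
combination bounds for the sensitivity analysis). Routine care is read
from a CD4-stratum × OI-history grid (224–1,224 / 275–938 EUR/month); OI
episodes cost 6,467–11,873 EUR one-off by type; the death month adds
7,548 / 14,351 / 11,985 EUR for no OI history, history older than 30
days, or an OI active or resolved within the previous month (the monthly
grid's reading of "within 30 days"). Utilities are 0.830 / 0.860 / 0.870
/ 0.900 for CD4 ≤50 / 51–100 / 101–200 / >200, and during an active OI
the OI utility (0.561 bacterial, viral, other; 0.652 protozoal, fungal)
replaces the CD4 utility via a minimum — an absolute health-state value
that must not *improve* a severely immunosuppressed month.

Costs and QALYs are discounted monthly at an annual 4% for the first 30
years and 2% thereafter, compounded piecewise-continuously so the factor
has no jump at the boundary; fractional-year exponents keep the factor
exact at year ends. Accrual happens at the start-of-month index (month 0
discounts to 1). There is no half-cycle correction; at a monthly cycle
the bias is negligible. A patient alive at the start of a month accrues
the full month.

## What is assumption and what is data

Everything printed above (efficacy, tariffs, utilities, discount rules,
the line algorithm, OI duration of three months, the 1,000-cell cap) is a
fixed model input. The remaining inputs are not published anywhere for
this population and are therefore explicit, overridable assumptions,
flagged `assumption` in `inst/extdata/base_case.yaml`:

* **Baseline cohort** — age ~ N(43, 10²) truncated to 18–75; 68% male;
  CD4 truncated-lognormal with median ≈200 cells/µL on 10–750; nobody
  suppressed at entry; 25% with an OI history. These emulate the entry
  criteria of a phase-III treatment-experienced trial population
  (adults failing therapy with multi-class resistance, moderately
  immunosuppressed). Baseline viral load is deliberately not modelled:
  no rate in the model depends on it.
* **OI hazards** — monthly per-type hazards rising as CD4 falls, doubled
  once a patient has an OI history. The scale was chosen once so that
  lifetime per-type incidence lands in the low single-digit percent
  range, i.e. OIs are a minor contributor, as expected for a cohort with
  access to suppressive therapy.
* **Mortality** — a synthetic abridged life table (annual probabilities
  by 5-year band and sex), deliberately elevated relative to a general
  population to reflect a comorbid HIV cohort, plus an annual
  HIV-attributable excess rising from 0.5% (CD4 >500) to 15% (CD4 ≤50),
  and an acute ×3 factor during active-OI months.
* **AE discontinuation** — 0.2%/month, constant across lines.
* **Switch and laboratory costs** — 400 EUR per line change and a flat 30
  EUR/month amortizing quarterly CD4/viral-load testing and genotyping at
  failure.
* **Terminal CD4 decline** — 3 cells/µL/month in the base case, chosen
  between the two scenario extremes (6 cells/µL/month worst case, 0
  optimistic).
* **Resistance acquisition** — the per-failure probability is the one
  genuinely calibrated quantity: `calibrate_resistance()` bisects on it
  until the simulated proportion of patients leaving line 1 alive
  without INI resistance matches a target (default tolerance 0.5
  percentage points). The bundled defaults (0.12 / 0.47) are analytic
  approximations of the calibrated values.

Because these inputs are assumptions, cohort-level absolute outcomes
(life expectancy, total cost) are reproducible in order of magnitude but
not digit-for-digit; the quantities the package pins down tightly are the
arithmetic identities, the paired-arm increments under common random
numbers, and the calibrated resistance proportions.

## Randomness, pairing, and reproducibility

All uniform draws are consumed as one fixed-size block per model month —
eleven columns per patient (death ×2, OI onset ×5, late failure, AE,
new-line response, resistance) — generated whether or not the patient is
still alive, from a stream seeded independently of the cohort sampler.
The first-line response draw is stored with the cohort itself. Two
consequences, both tested:

* **Determinism**: identical `(arm, parameters, n, seed)` give identical
  results, across runs and platforms.
* **Common random numbers**: patient *i* sees the same draws in both
  arms and in every perturbed scenario, so paired differences reflect
  parameters, not sampling noise. Two pharmacologically identical arms
  produce exactly zero increments, and a cost-only perturbation leaves
  the QALY delta bit-identical.

This is a month-major implementation of per-patient draw substreams: the
guarantee (patient-wise identical draws across compared settings) is the
same, and it vectorizes across the cohort.

## Outputs and analyses

`run_cohort()` returns per-arm means (costs by component, discounted and
undiscounted life years and QALYs, time per line, OI and AIDS outcomes,
death causes, post-first-line resistance status) with Monte Carlo
standard errors on the key outcomes; `compare_arms()` produces the
incremental table and the ICER from unrounded means, with exhaustive
dominance classification over the four delta-sign quadrants (a dominant
strategy is cheaper and more effective; the ratio is reported only when
it is meaningful). `run_dsa()` re-runs both arms at each parameter bound
and orders results by ICER range (tornado order); `run_structural_scenarios()`
covers the 15-year horizon, 1-month OI duration, no-resistance, 0%/6%
discounting and the two terminal-decline variants;
`price_sweep()` scales only the DTG drug component (not its OBT).
"Progression to AIDS" is reported using a CDC-like proxy — first OI or
first month with CD4 below 200 cells/µL (counting entry) — since the
outcome list does not define it.

## Numerical choices and degenerate inputs

* Truncated baseline distributions sample by rejection (shape-preserving
  near bounds) with a resample cap; a degenerate `min == max` interval
  short-circuits to the constant.
* OI type allocation is exclusive with a fixed order (bacterial, fungal,
  protozoal, viral, other) so runs are reproducible; one active OI at a
  time.
* The week-48 response is drawn at line start but a non-responder
  switches at month 12, accruing a full year of the line's cost —
  matching the trial's week-48 endpoint.
* CD4 strata are left-open on their upper bounds (a count of 500 is
  "351–500"; anything strictly above 500 is ">500").
* Bisection in `calibrate_resistance()` stops at a 0.5-point proportion
  tolerance; with a fixed seed the objective is a deterministic monotone
  step function, so convergence is guaranteed whenever the target lies in
  the attainable range (the floor — reached at probability one — is
  reported in the error otherwise).
* An unattainable horizon (entry age at the cap) yields zero accruals
  rather than an error; dead patients never transition, and censored
  survivors keep cause `"censored"`.

## Problem sizes

The production default is 500,000 patients per arm. The bundled analyses
and tests use smaller cohorts chosen for their purpose: 50,000 patients
for the property suite and for resistance calibration (Monte Carlo
standard error on the no-resistance proportion ≈0.15 percentage points),
a few thousand for paired-increment and monotonicity checks where common
random numbers remove most of the variance, and single scripted patients
for the ledger oracle. The sensitivity-analysis helpers default to
10,000 patients per run, enough to rank parameters by ICER range.

## Known limitations

* Background viral load is carried descriptively but drives nothing.
* OBTs enter only through their pooled monthly cost; individual drug
  components are not modelled.
* No probabilistic sensitivity analysis is provided; uncertainty is
  explored through one-way and structural analyses only.
* The mortality and OI-hazard assumptions reproduce plausible magnitudes,
  not a specific cohort's rates; absolute life expectancy and cost totals
  inherit that uncertainty, and passing tests demonstrate internal
  consistency and calibrated targets, not agreement with any real-world
  registry.
* The comparator arm represents sequencing in the absence of the
  intervention drug; scenarios with the intervention recycled into the
  comparator algorithm are out of scope.
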