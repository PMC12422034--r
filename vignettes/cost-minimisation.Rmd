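---
title: "Cost-minimisation analysis of integrated chronic care: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-minimisation analysis of integrated chronic care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intecost)
```

## The problem

Chronic care for HIV, hypertension (HTN) and diabetes (DM) in much of
sub-Saharan Africa is delivered through *vertical* clinics: one clinic,
one condition, with separate waiting areas, clinicians, laboratories and
pharmacy queues. A person living with two or three of these conditions
must attend one visit per condition. *Integrated* clinics manage all
three conditions at a single site with shared registration, staff and
dispensing. When a cluster-randomised comparison establishes that
clinical outcomes are equivalent between the two models, the economic
question reduces to a **cost-minimisation analysis**: which model is
cheaper, for whom, and by how much at national scale?

`intecost` implements that analysis as a tested pipeline from a
**societal perspective** — provider costs plus patient and household
caregiver costs — with a synthetic cluster-trial generator whose ground
truth is known, so every stage can be validated end-to-end without access
to restricted participant-level data.

## The costing model

### Money primitives

All arithmetic is carried out on `money` vectors that carry a currency
(UGX, TZS or international dollars, INTD) and a price year. Mixing units
is an error, never a silent coercion. The reporting pathway is always

1. inflate local-currency amounts to 2021 prices by a CPI ratio,
2. divide by the country's 2021 purchasing-power-parity rate
   (Int\$1 = UGX 1310.6 = TZS 890.58).

Capital purchases enter costs as an equivalent annual cost using the
standard annuity factor $(1-(1+r)^{-L})/r$ at $r = 3\%$ (straight-line at
$r = 0$). Useful lives are configurable per item; the generator's default
is 5 years, a common assumption for clinical equipment.

### Provider costs

Provider costs per participant-visit combine:

* **Top-down** allocation: monthly personnel and overhead pools plus
  annuitized capital / 12 are divided over the facility's condition-clinic
  streams in proportion to weighted monthly caseload
  (`allocate_top_down()`). Stream weights encode relative resource
  intensity; with equal weights every visit costs the same.
* **Bottom-up (ingredients)** costing: units of medication and
  diagnostics dispensed times unit prices (`ingredients_cost()`).

The comorbidity rules are the heart of the model
(`provider_visit_costs()`):

* *Integrated care, multimorbid, HIV-containing*: facility components
  (personnel, overhead, capital) are charged **once**, at the HIV-alone
  rate — the shared clinic serves all conditions in one contact.
* *Integrated care, HTN+DM (no HIV)*: no explicit rule is stated for this
  combination; we charge the **costliest constituent clinic once**. This
  is our own design choice, made because the shared-clinic logic (one
  registration, one consultation stream) applies equally, and because it
  reproduces the observed pattern where the integrated HTN+DM per-visit
  cost sits near the single-condition rates while the vertical HTN+DM
  cost approximates their sum.
* *Vertical (standard) care, multimorbid*: a "visit" is defined as the
  composite of one clinic visit per condition, so facility components are
  **summed** across constituent conditions.
* Medication and diagnostics are always summed over all of the
  participant's conditions, in both arms.

A direct consequence, covered by tests: single-condition visits cost the
same under either arm given the same inputs, and the integrated
multimorbid facility components equal the same facility's HIV-alone
components exactly.

### Patient and societal costs

Patient costs per visit (`patient_visit_costs()`) sum six components:
self-reported medication, other-medical and travel expenses, plus travel,
facility and childcare time valued at an hourly rate. Time is valued for
everyone regardless of employment status, at

$$\text{hourly value} = \frac{\text{monthly basis, 2021 prices}}
  {\text{days per month} \times \text{hours per day}}$$

with the conservative base case of mean per-capita consumption, 30 days
and 8 hours. For multimorbid participants in vertical care, reported time
quantities are **multiplied by two** before valuation, reflecting the
separate clinic visits their conditions require. Two further modelling
choices were genuinely open and are exposed as flags:

* `double_travel_expense` (default `TRUE`): the stated rule doubles only
  time, but a second physical trip implies a second fare, so the travel
  *expense* is doubled too by default; disable to double time only.
* `time_multiplier = "n_conditions"`: a participant with three conditions
  arguably needs three visits, not two; the default `"two"` mirrors the
  stated rule, the alternative is available for exploration.

Medication and other-medical expenses of vertical-care participants are
replaced by the integrated-arm group mean for the same profile at an
equivalent facility level (falling back to the country–profile mean, then
to the self-report, with a logged notice). Societal cost is the
record-wise sum of provider and patient totals.

### Arm comparison

Per-visit costs are compared with a Welch unequal-variance $t$ test
(Satterthwaite degrees of freedom, two-sided, 5% level), per
(country, profile, perspective) cell plus pooled single-condition and
multimorbid contrasts (`compare_all()`). Welch is used rather than the
pooled-variance test because group SDs differ visibly between arms and
profiles; a pooled test is recoverable as the special case of equal
sample variances and sizes. Facility-level clustering is deliberately
**ignored** in these tests, mirroring the analysis convention for
within-trial cost tables; consequences for the synthetic-data tests are
discussed below.

### Scale-up and budget impact

National annual cost per profile and arm is
`mean monthly cost x 12 x prevalent count x proportion x coverage`
(`annual_cost_at_scale()`, `national_totals()`). Each profile draws on
the prevalence pool of its lead condition (HIV if present, else HTN, else
DM) and the pool is split across its profiles using the costed sample's
condition mix, so proportions within a pool sum to one. Budget impact
divides totals and the integrated-minus-standard difference by current
health expenditure (CHE) and GDP (`budget_impact()`). Percentages are
rendered to two decimals, and the *rendered* difference row is computed
from the rounded arm percentages so a printed table is always internally
consistent — full-precision values are returned alongside.

A reference table of published-magnitude national totals ships with the
package (`reference_scaleup()`); reconciliation tests verify that the
per-profile rows reproduce the grand totals exactly for Uganda (both
arms) and Tanzania (integrated), with the Tanzania standard column
carrying a documented ±2 Int\$ printed-rounding discrepancy, and the
overall difference likewise within 2 Int\$ of its printed value.

### Sensitivity analyses

Three deterministic frameworks (`apply_uplift()`, `two_way_grid()`,
`time_valuation_variants()`):

1. **Uplift**: integrated-arm personnel and overhead components scaled by
   1.10 / 1.20 / 1.50. Capital is *excluded* by default because the
   stated variation names personnel and overheads only; a flag includes
   it. Factor 1 is bit-identical to the base case.
2. **Two-way grid**: prevalence-mix proportions and mean monthly costs
   varied over {low, point, high} of their 95% CIs — nine cells;
   perturbed proportions are renormalised to preserve the original mass.
   The summary reports min/max difference and an `all_cost_saving` flag.
3. **Time valuation**: 22 working days instead of 30 (scales every time
   cost by exactly 30/22) and median monthly salary instead of mean
   consumption, with a significance-concordance table against the base
   case.

## The synthetic world

The generator (`generate_trial()`) emulates a two-country trial: 6714
participants across 17 Ugandan and 15 Tanzanian facilities randomised to
arms by balanced permutation within country, 23.62% multimorbid, a
questionnaire sub-sample of 2708/6714 taken first-enrolled per facility
(emulating consecutive administration that was stopped at an interim
review), and monthly chronic-care visits (Poisson, mean 12/year).

Cost components are drawn from a **gamma** family parameterised by mean
and SD (lognormal available) — non-negative and right-skewed like real
cost data; zero SD degenerates to the mean exactly. Provider targets are
specified per (country, single condition) as per-visit totals anchored at
the published integrated-arm magnitudes (e.g. Uganda HIV 168.85 (45.49)
Int\$); `calibrate_components()` splits each total into
personnel/overhead/capital/medication/diagnostic shares
(0.50/0.15/0.05/0.25/0.05), assigns between-facility variation
(CV 0.10 by default) to the facility share, visit-level CV 0.5 to
diagnostics, and gives the medication component the residual variance so
the marginal total has exactly the requested moments. Multimorbid
profiles are **emergent** from the care-model rules rather than directly
targeted, which keeps the ground-truth arm difference analytically known:
for an HIV+HTN participant it is exactly the HTN facility rate.

Facility ledgers are built by **inversion**: per-visit rates are drawn
around the country targets, then monthly pools are set to rate × monthly
caseload, so `allocate_top_down()` recovers the generating rates exactly.
Patient questionnaire targets (expenses per condition, travel/facility
hours, childcare propensity) were chosen once at the order of magnitude
of published patient-cost tables and are documented in
`trial_config()`; they are not calibrated to reproduce any printed cell.

What the generator does **not** emulate: seasonal visit patterns,
facility-level case-mix correlation, medication stock-outs (which inflate
real NCD patient costs), COVID-era service disruption, or measurement
error in self-reports. A green test therefore establishes correctness of
the *pipeline*, not realism of any particular cell value.

### Clustering and the recovery harness

Ignoring facility-level clustering (as the per-visit t tests do) means
that with few facilities and non-zero between-facility variance, CI
coverage of the true arm difference degrades — a property of the
estimator, not a bug. The parameter-recovery acceptance harness therefore
sets `facility_cv = 0`, isolating the estimator chain from design-effect
under-coverage; with iid visits the Welch 95% CI covers the true 18.67
Int\$ multimorbid saving at its nominal rate (~95%, tested against a 90%
floor over 200 seeds). The default world keeps `facility_cv = 0.10` for
realism, and a facility-level bootstrap would be the natural extension if
cluster-robust inference were needed.

## Numerical choices

* Full floating-point precision everywhere; rounding happens only at
  rendering (2 decimals for per-visit Int\$ and percentages, integers for
  national totals).
* Degenerate inputs: zero-SD draws return the mean; `sd` of a singleton
  group is reported as 0 with a `single_obs` flag; zero-societal-cost
  visits are excluded from the provider-share statistic with a logged
  count; empty comparison cells are flagged not-estimable and the
  pipeline continues.
* Constant-sample Welch comparisons (SE = 0) return p = 1 when the means
  agree and p = 0 otherwise, with a degenerate CI at the difference.
* Ties in the "costliest constituent clinic" rule resolve to the first
  condition in the canonical HIV, HTN, DM order.
* Determinism: every random quantity flows from the single seed passed to
  `generate_trial()` / `run_pipeline()` via an isolated RNG scope.

## Default economy parameters

PPP rates are the stated 2021 conversion factors. CPI series, monthly
consumption (UGX 120,000 / TZS 70,000) and median salaries
(UGX 200,000 / TZS 150,000) are editable placeholders of realistic
magnitude, *not* national statistics. CHE and GDP defaults were inverted
from the reference scale-up table's printed percentage rows (e.g. Uganda
CHE ≈ Int\$4.33bn makes a 228.5m saving ≈ 5.3% of CHE) so budget-impact
output lands on the published scale; real analyses must supply official
values. National prevalence and coverage defaults in
`default_run_config()` are likewise synthetic placeholders, with target
coverage 95% for HIV and 80% for HTN and DM.

## Worked example

```{r example, eval = FALSE}
cfg <- default_run_config(seed = 1, trial = trial_config(
  n_participants = 1200, n_facilities = c(Uganda = 8, Tanzania = 8),
  visits_per_year = 6))
bundle <- run_pipeline(cfg, out_dir = "report")
subset(bundle$comparisons, group == "pooled multimorbid")
bundle$scaleup$Uganda$totals
```

Every empirical statement in this vignette is recomputed by the test
suite (`tests/testthat/`) or the acceptance script
(`scripts/acceptance.R`); neither asserts any number the package does not
itself compute at run time.

## Known limitations

* Cost t tests ignore clustering by design (see above).
* The scale-up model is static: no demographic projection, uptake
  dynamics, or multi-year discounting (12-month horizon).
* No QALY/DALY outcomes: the analysis is a cost-minimisation, valid only
  where outcome equivalence has been established elsewhere.
* Questionnaires administered before a visit ends under-capture facility
  time; no correction is defined or applied.
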