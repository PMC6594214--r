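---
title: "Methods: a CKD decision-support engine and its cluster-trial machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a CKD decision-support engine and its cluster-trial machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdcdss)
```

# What this package models

Early chronic kidney disease (CKD) is mostly managed in primary care, where
guideline-concordant actions — statins, renin-angiotensin blockade for
albuminuria, potassium surveillance, timely nephrology referral, patient
education — are applied inconsistently. `ckdcdss` implements an electronic
clinical decision support system (eCDSS) for this setting, built around
*triple-marker* testing (serum creatinine, serum cystatin C, and urine
albumin-creatinine ratio, ACR), together with the full machinery of a
pragmatic cluster-randomized trial of such a system: synthetic EHR
generation, cohort selection, provider-level randomization, alert
(best-practice-advisory, BPA) trigger simulation, safety surveillance,
implementation-funnel metrics, and the cluster-design power arithmetic.

Everything runs on synthetic data, so the whole pipeline is testable without
patient records.

# Renal calculators

Three published equations are implemented as pure functions:

* `egfr_creatinine()` — CKD-EPI 2009. The 2009 race coefficient sits behind
  `race_coefficient_enabled`, default **off**. The flag exists because which
  convention a source laboratory used in the study era is generally unknown;
  eligibility work recomputes eGFR from raw creatinine rather than trusting
  a stored eGFR column, and the flag records the choice explicitly.
* `egfr_cystatin()` — CKD-EPI 2012 cystatin C.
* `kfre_5yr()` — the 4-variable kidney failure risk equation (age, sex,
  eGFR, ACR), 5-year horizon, North-American baseline survival 0.9240. The
  4-variable form is the natural choice here because its inputs are exactly
  what the triple-marker workflow provides. The engine feeds it eGFR_Cys —
  the workflow's risk-stratification GFR — though callers may supply any
  eGFR.

eGFR values are never rounded before threshold comparisons; all thresholds
compare full-precision values, which keeps decisions independent of printing
conventions.

# The rules engine

Risk stratification is the published dichotomy: **high** risk iff
eGFR_Cys < 60 mL/min/1.73m² and/or ACR > 30 mg/g; otherwise **low**. The
printed clauses are both strict, which leaves the exact boundary
(eGFR_Cys = 60 with ACR = 30) in neither; this package assigns it **low**,
and every comparator lives in one `cdss_thresholds()` object so the dialect
is visible, overridable, and testable.

Low-risk patients receive exactly one action: repeat triple-marker testing
in 6 months. High-risk patients receive the union of five care domains:

1. *Cardiovascular risk reduction* — statin initiation at age ≥ 50 when not
   already on one.
2. *Potassium management* — the source workflow specifies only "diet and
   diuretic recommendations" without cutoffs. We use clinically conventional
   tiers: K in (5.0, 5.5] mEq/L → dietary counseling; K > 5.5 → counseling
   plus diuretic adjustment (and the referral criterion below). Both edges
   are configurable. A never-measured potassium leaves these rules unfired
   and flagged `unassessed` rather than silently negative.
3. *Proteinuria management* — ACR > 30 mg/g triggers ACEi/ARB *initiation*
   when none is active, *titration* when one is.
4. *Nephrology referral* — any of: eGFR_Cys < 30 (one confirmed panel; a
   repeat-confirmation mode is a config option, since the workflow measures
   cystatin once); K > 5.5; ACR > 300; SBP > 150 mmHg despite ≥ 3
   antihypertensive classes including a diuretic; or > 3% 5-year kidney
   failure risk. All strict, as printed. The referral action appears iff at
   least one criterion is met — an engine invariant the tests check by
   brute force against an independent table-driven oracle on 10,000 random
   states.
5. *Patient education* — three content keys (CKD general, NSAID avoidance,
   diet) emitted with the patient's preferred language; content authoring is
   out of scope.

# Cohort selection

Inclusion: age 18–80 at the index date; preferred language English, Spanish
or Chinese; two **outpatient** eGFR_Cr values in 30–59 mL/min/1.73m² at
least 90 days apart with the later inside the 12 months before the index
date; and a PCP visit within 18 months. Automated exclusions: deceased,
ESRD, ≥ 2 nephrology visits in 12 months, transplant, dementia. Manual
exclusions (pregnancy, short life expectancy, severe heart failure, PCP
discretion…) are consumed as an input table because such criteria are
unreliably captured in structured EHR data; opt-outs likewise.

Dialect decisions, fixed and documented so results are bit-stable:

* the 30–59 band is inclusive at both ends; "at least 90 days" is a date
  difference ≥ 90; "within 12 months" is within 365 days strictly before the
  index date; "18 months" is 548 days; day granularity throughout, intervals
  half-open `[start, end)`.
* both members of the qualifying pair must be outpatient values (the
  stricter reading); an inpatient result can never rescue eligibility.
* among multiple qualifying pairs the evidence pair is the one with the most
  recent later date, ties broken by the earliest first date.
* eGFR for eligibility is recomputed from stored creatinine through
  `egfr_creatinine()` — a single source of truth.

The funnel summary counts each removed patient once, in the bucket of the
first rule that removed them (cascade order: inclusion, automated, manual,
opt-out), while the per-patient decision retains every triggered code.

# Synthetic EHR generation

`generate_population()` emits linked tables plus a ground-truth sidecar
(true eligibility label and reason, latent cystatin/ACR, true risk tier)
used only by tests. Design choices:

* A configurable fraction of patients (default 0.6) is constructed eligible
  by inverting the CKD-EPI 2009 equation to plant creatinine values with
  known eGFR; each remaining patient violates **exactly one** criterion, so
  every exclusion path is exercised and decisions can be asserted exactly
  (100% label agreement on noiseless data).
* Defaults mirror the study population: 81 providers (47 attending, 31
  resident, 3 nurse practitioners, apportioned by largest remainder so the
  counts are exact), mean age ≈ 70 (SD 9, truncated 30–80 for in-range
  patients), hypertension 72%, diabetes 38%, hyperlipidemia 58%, statin 67%,
  ACEi/ARB 61%, language 90/7/3 English/Chinese/Spanish.
* Systolic BP at each ambulatory visit is grand mean (128 mmHg) + a Gaussian
  provider effect with variance ρσ² + a Gaussian residual with variance
  (1−ρ)σ², with σ = 5 mmHg and ρ = 0.025 by default — the same
  variance-components algebra the power analysis assumes, so the ANOVA
  estimator `icc_anova()` recovers ρ.
* Visit frequency is not reported for the source setting; the default of 3
  ambulatory visits/year is an assumption, configurable via
  `visits_per_year`.
* What the generator does **not** emulate: realistic assay noise beyond the
  planted values, care-seeking correlated with disease severity, panel
  changes over time, coding errors, or missingness mechanisms. Passing
  tests therefore demonstrate correctness of the *logic* under the stated
  model, not robustness to real-world EHR mess.

# Trigger state machine

The BPA arms when all three panel results are in (`labs_complete_time()` =
the latest collection timestamp), displays at the first own-PCP visit
afterwards, and — if not signed — at up to 2 additional own-PCP visits
(3 display opportunities total; the cap is configurable). Visits with any
other provider never trigger. "Opened" means the accept click; hovering over
the alert is not counted, matching how adoption can actually be measured.
Signing is absorbing. In the eCDSS+ arm, signing schedules a pharmacist call
due within 14 days.

`simulate_trial()` drives every intervention patient through Bernoulli
behavior gates (lab completion, PCP visit, open, sign, call completion). By
default each passing patient receives one eligible visit, so expected
funnel proportions equal the gate probabilities — convenient for
calibration; multi-display behavior is exercised through
`process_encounter()` directly. Re-displays recompute the recommendation
snapshot (the risk tier stamped on each event), and the log is a
deterministic function of inputs and seed.

# Safety surveillance

`weekly_review()` implements the nephrologist's weekly screen: eGFR_Cr
decline > 30% from baseline (baseline = most recent outpatient value before
enrollment; missing baseline → rule `unassessed`), ACR ≥ 1000 mg/g
(inclusive, as printed), creatinine/cystatin eGFR discordance > 30% on a
same-panel pair, and nephrology-referral non-adherence after a 90-day lag.
The discordance denominator is eGFR_Cr — the routinely reported value — but
is configurable, since the ratio's base is not pinned down; the referral
lag likewise. The function is pure, so re-running a review week cannot
duplicate flags.

# Outcome metrics

`funnel_report()` computes the RE-AIM reach/adoption funnel with the
denominators the trial reports (completion over enrolled, visit over
completers, opened over visited, signed over opened, call over signed
eCDSS+), each with explicit numerator/denominator, plus
"of all intervention participants" variants; zero denominators yield `NA`,
never a division error.

Blood-pressure outcomes: baseline = most recent ambulatory measurement
strictly before enrollment; endpoint = last in-period measurement carried
forward (LOCF); control = SBP < 140 **and** DBP < 90, both strict (the
threshold predates the 2017 guideline change and matches KDIGO).
*Sustained control* requires ≥ 2 **consecutive BP-measured visits** under
the threshold: visits without a BP measurement are invisible to the
sequence, because calendar adjacency is not well defined for irregular
primary-care visits. That reading is a design decision and is configurable
at the threshold level.

# Randomization

"Block randomization at the provider level based on panel size" is realized
as: sort providers by eligible-panel size (descending, ties by provider id),
cut into consecutive blocks of 3, permute the three arm labels within each
block. This is the simplest mechanism that balances both provider counts
(exactly, up to a final short block) and expected patient totals; the exact
procedure used by any given trial statistician is typically unpublished, so
this is one admissible implementation, and the tests verify the balance
property itself (blocked beats simple randomization stochastically on
max pairwise patient-count imbalance across 1,000 seeds).

# Power analysis

For a balanced two-arm comparison of cluster means,

$$\delta = \left(t_{1-\alpha/2,\,2(k-1)} + t_{\text{power},\,2(k-1)}\right)
\sigma \sqrt{\frac{2\,[1 + (m-1)\rho]}{k\,m}}$$

with $k$ clusters per arm, $m$ patients per cluster, intraclass correlation
$\rho$ and total SD $\sigma$. With the study design ($k=23$, $m=15$,
$\rho=0.025$, $\sigma=5$, $\alpha=0.05$, power 0.80) this gives 1.2674 →
**1.27 mmHg**. The t quantiles on $2(k-1)$ degrees of freedom are the
convention that reproduces that printed value — normal quantiles give
≈ 1.24 — so t is the default, with `df_method = "z"` available.

`simulate_power()` checks the same design by Monte Carlo: cluster means with
variance $\rho\sigma^2 + (1-\rho)\sigma^2/m$, a two-sample t test on cluster
means per replicate. Testing cluster means is exactly valid under the
balanced Gaussian model the design stage assumes; fitting GEE belongs to the
analysis stage and is out of scope here.

```{r power}
d <- power_design()
detectable_difference(d)
simulate_power(d, delta = 1.27, n_reps = 2000, seed = 1)$power
```

# Numerical and testing notes

* All randomness flows through explicit seeds; generation, simulation and
  randomization restore the caller's RNG state.
* Problem sizes used by the test suite — e.g. 10,000 random states for the
  rules-engine oracle, 1,000 random encounter streams, 200 clusters × 15
  patients × 3 ICC values for variance-component recovery, 5,000 power
  replicates — were chosen to make Monte-Carlo standard errors small
  relative to the tolerances being asserted (3 MC SEs) while keeping the
  suite quick on a laptop.
* Stochastic assertions use 3-standard-error bands around analytically
  known targets, never bands fitted to observed output.
* The reference participant-flow fixture (`example_trial_fixture()`) is
  built in code, with stage membership nested within arm, and is labelled
  synthetic: it encodes reported stage *counts*, not patient data.

# Known limitations

* The generator's cystatin/ACR values are latent per-patient constants;
  longitudinal progression is not modeled.
* Potassium cutoffs for the diet/diuretic tiers and the discordance
  denominator are conventions, not published constants; both are
  configurable and defaulted as documented above.
* Provider behavior in `simulate_trial()` is exchangeable Bernoulli —
  no provider-level heterogeneity in alert uptake.
* The package computes design-stage and implementation metrics; it does not
  fit the trial's GEE outcome models.
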