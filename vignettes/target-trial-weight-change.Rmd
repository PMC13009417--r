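---
title: "Emulating a trial of antihypertensive initiation and weight change: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a trial of antihypertensive initiation and weight change: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The causal question and the estimation strategy

Antihypertensive drugs differ in their effect on body weight: beta-blockers
tend to cause modest gain, ACE inhibitors and thiazides modest loss. A
randomized comparison across the common first-line monotherapies is
infeasible, so the question must be answered from electronic health records
(EHR), where three biases dominate:

1. **Baseline confounding** — prescribers choose drugs partly on weight-
   related characteristics (thiazide and ARB initiators are heavier,
   beta-blocker initiators leaner and younger).
2. **Informative outcome measurement** — weight is recorded only at
   encounters, and who shows up each month depends on characteristics that
   also predict weight change. Only a minority of patients have a weight
   recorded at any given landmark month.
3. **Informative nonadherence** — patients stop therapy at rates that
   depend on their covariates and on their own interim weight trajectory,
   so restricting to continuous users selects a biased subpopulation.

`trialemu` implements the standard target-trial-emulation answer. The
hypothetical trial enrolls adults aged 20–80 with no prior antihypertensive
use who initiate exactly one of seven drugs (lisinopril — the reference —
amlodipine, atenolol, hydrochlorothiazide, losartan, metoprolol,
propranolol); the outcome is weight change from baseline at 6, 12 and 24
months. Two effects are estimated: the *initiation-only* (IO) effect
(analogous to intention-to-treat) and the *per-protocol* (PP) effect of
initiating **and** adhering, in which patients are artificially censored
when they deviate from therapy, with a one-month grace period.

Estimation proceeds by inverse probability weighting (IPW) of a repeated
outcomes marginal structural model (MSM):

* a pooled logistic model estimates each person-month's probability of
  having a weight measured; measured rows are weighted by `1/p` (per-month,
  non-cumulative, because outcome missingness is intermittent);
* in PP mode a second pooled logistic model estimates the monthly hazard of
  deviating; a row at month *t* is retained only if the patient survived
  the deviation hazard through month *t − 1*, so it receives the inverse of
  that cumulative product (cumulative, because artificial censoring is
  monotone);
* combined weights are truncated at their empirical 99th percentile;
* the weighted outcome model regresses monthly weight change on arm
  indicators, a restricted cubic spline in month with 4 knots, arm × spline
  interactions, and baseline covariates;
* per-arm means are standardized by g-computation: every cohort member's
  arm is set to the target arm, the fitted value at the target month is
  averaged over the cohort's baseline-covariate distribution;
* contrasts subtract the reference arm; the risk of gaining ≥ 5% of
  baseline weight is handled identically with a logistic outcome model, and
  reported as a risk ratio versus the reference;
* all interval estimation is by patient-level bootstrap (percentile 2.5/97.5;
  production default 1000 replicates), with every weight model refit inside
  each replicate so the estimation uncertainty of the weights propagates.

## The 30-day person-month grid

All dates are integer day offsets from a fixed epoch (day 0 = 2010-01-01).
Month *t* of follow-up covers days `[30t, 30(t+1))` from the initiation
day; "6/12/24 months" means `t = 6, 12, 24`. Month 0 is the baseline
itself: its weight change is identically zero and never enters the outcome
fit. Within a month, multiple weights average before differencing against
baseline. Follow-up ends at 24 months or death, whichever is first; the
last retained month is `floor(death_day/30)`.

The covariate `lwc` ("last measured weight change") carried by the panel is
deliberately **lagged**: at month *t* it is the most recent measured change
from months strictly before *t* (0 before any follow-up measurement). This
is the information actually available when month *t*'s measurement and
adherence processes fire, and it is the timing at which the weight models
condition.

## Eligibility and baseline

The exclusion cascade is evaluated in a fixed documented order so attrition
logs are deterministic: age (20–80 at initiation) → prior antihypertensive
use → polytherapy at initiation (two study drugs on the first day) → no
encounter ≥ 180 days before initiation → cancer `[-365, +30]` → pregnancy
`[-365, 0]` → bariatric surgery `[-1095, +30]` → heart failure `[-365, +30]`
→ anti-obesity/steroid/stimulant fills `[-30, +30]` → no baseline weight in
`[-90, 0]` → missing sex or race/ethnicity → no blood pressure in
`[-180, 0]`. All windows are closed day ranges. Each rejected candidate
gets exactly the first reason that fails.

Baseline weight is the plausible measurement closest to but not after
initiation within 3 months (same-day duplicates averaged; a day-0
measurement counts). The recent-weight-change category (±0.5 kg thresholds)
anchors on the measurement closest to day −180 within `[-270, -90]`;
patients with no anchor are classed "stable". In place of a full EHR
anthropometric cleaning pipeline the package applies a desk-scale
plausibility filter — weights outside 25–350 kg and jumps exceeding
30 kg per 30 days (same-day repeats are treated as duplicates unless they
disagree by more than the threshold) — documented as a stand-in, not a
reimplementation, of production-grade cleaning.

## Adherence reconstruction and the grace period

A fill covers `days_supply × (1 + refills)` days from its fill date; when
`days_supply` is blank but quantity is known, a constant one-unit-per-day
dose is assumed (configurable); when all supply fields are blank, one month
per dispensing. Roughly half of real prescriptions lack usable supply
fields, so blanks are imputed from the same patient's same-drug fill
nearest in time (ties to the earlier donor); a fill with no donor falls
back to the one-month minimum. Overlapping coverage unions by default; a
`stockpile` flag shifts overlapping fills to end-to-end consumption.

Deviation is scanned at day resolution: if the first uncovered day is `E`
and coverage does not resume strictly before `E + 30`, the deviation day is
`D = E + 30` and the censor month `floor(D/30)`. A gap of exactly the grace
length counts as deviation ("one month without, but no longer"). Patients
who die before completing a deviation are treated as dying adherent —
follow-up truncation applies, not artificial censoring — otherwise the end
of a refill chain at death would masquerade as nonadherence. Initiating a
*second* study drug does not censor by default (deviation =
discontinuation); a `censor_on_switch` flag provides the stricter reading,
since the protocol text pins down only the go-without rule.

One indexing convention deserves note: a row at month *t* is in the PP risk
set iff the patient survived the stop hazard in months `1..t−1` (the grace
period shifts the censor month one past the stop month), so the censoring
weight at month *t* is the inverse product of fitted continuation
probabilities through *t − 1* and equals 1 at month 1. Under a constant
monthly hazard *h* the weights are `(1−h)^−(t−1)`.

## The synthetic EHR generator and its ground truth

Analyses of this design run on restricted multi-site EHR networks whose
extracts cannot be redistributed, so the package ships a generator whose
causal structure is known exactly; every downstream stage is tested
against that truth.

* **Population.** Covariates loosely match published baseline profiles of
  US antihypertensive-initiator cohorts (mean age 53.3 (SD 14), BMI 30.6
  (SD 7.3), 56% female, 72% White, 63% hypertension diagnoses). These are
  descriptive anchors, not calibration targets.
* **Trajectories.** Under full adherence, arm *d*'s mean weight change at
  month *t* is the saturating exponential
  `mu_d(t) = theta_d (1 − exp(−t/tau_d))` — smooth, monotone, with
  closed-form truth at any month. Defaults place the six-month means near
  the per-arm absolute changes reported for these drugs (lisinopril
  `theta = −1.10` kg … metoprolol `+1.10` kg; `tau = 6` months for all).
  On top sits a constant obesity shift (`covariate_effect`, default
  −1.2 kg from month 1 onward, the scale suggested by obesity-stratified
  results for these drugs). Making the shift constant across follow-up
  months keeps the additive-covariate outcome model exactly specified, so
  recovery failures in tests indicate real pipeline defects rather than
  model misspecification. Weight *levels* add a between-patient random
  intercept (SD 2 kg) and within-patient measurement noise (SD 1.5 kg).
  The documented obesity flag is derived from the *measured* baseline
  weight, exactly as the cohort builder later derives it, so the
  generator's confounder and the analyst's covariate coincide.
* **Confounded assignment.** A multinomial logit on obesity, age and sex
  with intercepts matched to observed prescribing shares (lisinopril 36%
  … atenolol 5%) and obesity coefficients following the observed gradient
  (thiazide/ARB initiators heavier; beta-blocker initiators leaner).
* **Informative measurement and discontinuation.** Monthly Bernoulli
  hazards on obesity, age and the lagged last measured weight change
  (defaults: measurement base rate 25%, stop base rate 5%/month). Because
  the outcome depends on obesity and shares measurement error with `lwc`,
  both processes plant real selection bias of roughly half a kilogram in
  unweighted means — large relative to Monte-Carlo error at the standard
  simulation size, so the debiasing checks have power.
* **Prescriptions.** One 30-day fill per adhered month, truncated at the
  simulated stop month; half the fills have all supply fields blanked
  (matching the reported completeness of real prescription data). Uniform
  30-day fills keep nearest-donor imputation exact and give the
  reconstructed censoring process an exact monthly-hazard representation;
  mixed 30/90-day chains, refill bundling, gaps and stockpiling are
  exercised in the adherence engine's randomized oracle tests instead.
* **Trajectories do not react to adherence.** The generator encodes a
  world where the planted trajectory persists after discontinuation, so
  the IO and PP estimands coincide and one closed-form truth serves both;
  the PP machinery is still fully exercised because censoring is
  covariate-driven and selective. This is a deliberate identification
  device, not a claim about pharmacology.
* **Ground truth.** Means and contrasts are closed-form
  (`theta_d(1−e^{−m/tau}) + delta·P(obesity)`); the 5%-gain risk
  integrates an exact normal-CDF expression over a large fixed-seed draw
  of the covariate distribution (the only Monte-Carlo ingredient, with
  error well below every tolerance used). The truth depends only on the
  configuration, not the seed.

## Numerical choices

* Weight-model probabilities are floored at `1e−6` before inversion;
  percentile truncation (default 99, inverse-ECDF order statistic so the
  cap is an observed weight) governs the extremes. Unstabilized weights
  are the default, matching the truncation-based handling of extremes;
  stabilized variants are available in the module API.
* The pooled logistic models are solved by Newton iteration on the frozen
  design matrix (compiled), warm-started from the point fit inside
  bootstrap replicates, with `stats::glm.fit` as the fallback path. Weight
  models error loudly on rank deficiency or separation-scale coefficients;
  the logistic *outcome* model is exempt from the separation guard because
  empty arm-month cells legitimately produce huge negative logits.
* The outcome model is weighted least squares via the normal equations
  (QR fallback with a descriptive aliasing error). No within-patient
  correlation structure is modelled; the patient-level bootstrap carries
  all interval estimation, and weight models are refit per replicate.
  Replicates are implemented as per-patient multiplicity weights on frozen
  design matrices — algebraically identical to resampling rows.
* Spline knots sit at the (0.05, 0.35, 0.65, 0.95) quantiles of the fitted
  rows' months and are held fixed across bootstrap replicates. Arm-by-time
  interaction uses the spline basis (an arm × month-dummy variant is
  available via `spline_spec(time_trend = "factor")`).
* Subgroup runs filter the eligible cohort before panel construction and
  rerun the identical pipeline; covariates that become constant within a
  stratum (e.g. obesity inside the obesity stratum) are dropped from the
  models with a message.
* Bootstrap seeds derive from one master seed (`boot_seed`) spawning one
  substream per replicate, so results are reproducible and independent of
  execution order.

## Standard simulation sizes

The package's own checks use 20,000 source patients (≈ 17,000 eligible)
for ground-truth recovery of means, contrasts and risk ratios; a
200-simulation × 2,000-patient × 200-replicate design for bootstrap
coverage of the month-6 reference-arm mean; and 1,000 randomized fill
histories for exact day-level agreement of the censoring scan with an
independent day-by-day simulator. Recovery is judged against three
Monte-Carlo standard errors (bootstrap-estimated); the planted selection
biases are sized to be detectable at many times that threshold.

## What passing tests do and do not show

The generator emulates confounded assignment, informative measurement,
covariate-driven discontinuation and missing supply fields — the biases
the design targets — under conditions where the adjustment model sets are
*correct*. Real EHR data add unmeasured confounding (prescriber
preference), out-of-system prescriptions and measurements, misclassified
new users, weight-data errors beyond the plausibility filter's reach, and
adherence that is not observable from prescribing records at all. Passing
recovery tests therefore demonstrates that the estimator implements its
estimand correctly, not that the estimand equals the causal effect in any
particular real dataset. Dose effects, polytherapy strategies,
survival-type outcomes and competing-risk handling of death are out of
scope; death simply truncates follow-up.
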