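---
title: "Modelling daily urine-biomarker telemonitoring for COPD exacerbation early warning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily urine-biomarker telemonitoring for COPD exacerbation early warning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`exalert` implements a complete analysis chain for predicting acute
exacerbations of COPD from daily home urine tests of an inflammatory
biomarker panel: discovery-stage screening of candidate markers on paired
stable/exacerbation samples, Bayesian state-space filtering of each
patient's daily series, rolling-window temporal features labelled with time
to exacerbation, a stepwise neural-network risk score, and traffic-light
decision rules evaluated at the event level. Because no patient-level data
are publicly deposited for this design, the package ships a synthetic
cohort generator that reproduces the statistical structure the analysis
assumes; every stage is exercised against it.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions that were
genuinely open.

## The synthetic cohort

`generate_cohort()` simulates one series per patient and marker on the
log10-concentration scale:

$$y_{t} = \beta_i + d_t + b_t + s_t + r_t + \varepsilon_t$$

* $\beta_i \sim N(\mu_0, \sigma_\beta^2)$ — a per-patient, per-marker
  baseline (`baseline_mean` = 2, `baseline_sd` = 0.3 log10 units).
* $d_t$ — slow random-walk drift (`drift_sd` = 0.005/day).
* $b_t$ — device-batch step offsets, piecewise constant over
  `batch_length` = 28-day batches with steps $\sim N(0, 0.05^2)$.
* $s_t$ — AR(1) day-to-day fluctuation with coefficient `ar_coef` = 0.7 and
  innovation SD `ar_sd` = 0.04.
* $r_t$ — the pre-exacerbation rise: for informative markers, a linear ramp
  from 0 at 13 days before a diagnosis to `shift_magnitude` = 0.3 log10
  units (a doubling of concentration) on the diagnosis day, then an
  exponential decay with half-life `recovery_days`/4 (42/4 = 10.5 days),
  emulating a six-week recovery.
* $\varepsilon_t \sim N(0, 0.04^2)$ — observation noise.

On the log10 scale an SD of 0.04 corresponds to day-to-day variation of
roughly ±10% of the local level on the linear scale, which is the prior
judgement the filtering model is built around. Missing days are drawn
completely at random with `missing_prob` = 0.12 (the observed daily-testing
compliance of such home-monitoring studies is near 88%), and the analysis
assumes missingness is non-informative throughout. Exacerbations arrive
with a constant daily hazard (`exac_hazard` = 0.003, matching a cohort
enriched for exacerbations, about 0.5 events/patient/6 months) and
successive events are separated by more than `recovery_days`.

The generator fans one global seed out to per-patient and per-series
substreams, so enlarging a cohort never perturbs existing patients. The
linear ramp is a stand-in: the true biological lead-in shape is unknown,
and nothing downstream depends on its exact form beyond being detectable
over a ~13-day lead-in.

What the generator does **not** emulate: diurnal urine dilution, assay
saturation, device failure modes, informative missingness (e.g. sicker
patients skipping tests), and correlated multi-marker flares. Passing tests
on this cohort therefore demonstrate the machinery recovers planted
structure of the assumed form — not clinical performance on real data.

## Discovery screening and the logistic panel

`screen_biomarkers()` applies, per marker, a two-sided paired t-test on
log10 concentrations together with the ROC AUC of exacerbation versus
stable values; a marker passes when (AUC ≥ 0.59 or ≤ 0.41) and p < 0.05.
The t-test scale is not dictated by the original analysis description; log10
is used for consistency with the filtering model. `fit_panel()` then runs
backward stepwise logistic regression: refit, drop the covariate with the
largest Wald p-value above 0.05, repeat until all survivors are significant
or one remains. Wald (not likelihood-ratio) criteria keep elimination cheap
and deterministic; ties are broken by dropping the lexicographically later
marker name so the path is invariant to candidate order. Perfect separation
aborts with an error rather than returning divergent coefficients.
`panel_score()` is the plain inverse-logit; the default reporting cut-off is
0.39 with the Youden-optimal cut-off available via `youden_cutoff()`.

## The dynamic linear model and causal filter

Each biomarker series gets a univariate non-homogeneous DLM with state
$(\mu_t, s_t, b_t)$:

$$y_t = \mu_t + s_t + b_t + \varepsilon_t,\qquad \varepsilon_t \sim N(0, V)$$
$$\mu_t = \mu_{t-1} + \omega^{(\mu)}_t,\quad
  s_t = \phi\, s_{t-1} + \omega^{(s)}_t,\quad
  b_t = b_{t-1} + \omega^{(b)}_t \mathbb{1}[\text{batch change at } t]$$

with four variances $(V, W_\mu, W_s, W_b)$ and one AR coefficient $\phi$.
Priors are inverse-gamma on each variance and uniform on $\phi \in (0,
0.99)$. Prior scales are set through the ±10% judgement: prior mean SD
0.04 log10 units for $V$ and $W_s$, a weaker 0.01 for the drift $W_\mu$,
and 0.05 for batch steps.

`fit_dlm()` is a Gibbs sampler (default 4,000 iterations, 1,000 burn-in,
thinning 2): the $(\mu, s)$ path is drawn jointly by forward-filtering
backward-sampling; the batch step innovations form a small conjugate
Bayesian linear regression given the state path (equivalent factorisation
of the same posterior that keeps the backward pass non-singular); variances
have conjugate inverse-gamma updates (with no batch changes, $W_b$'s
posterior is exactly its prior); $\phi$ takes a random-walk Metropolis step
(proposal SD 0.05) targeting the full conditional including the stationary
prior on $s_0$; and missing observations are imputed from their conditional
normal each sweep, which is valid under non-informative missingness. All
draws run through R's RNG, so a seed fixes the entire chain. Model fitting
uses the whole series; feature extraction later uses only causal filtered
values — both behaviours are preserved deliberately.

`kalman_filter()` is the strictly causal filter: the reported value on day
$t$ is a function of observations on days ≤ $t$ only, with missing days
handled by pure prediction. Its means match brute-force conditioning of the
joint multivariate normal to 10⁻⁸ on short series (tested), and its
prediction-error-decomposition likelihood matches the joint density
likewise.

Which state combination is "the filtered value" was an open choice. The
default reports $\mu_t + s_t$ (physiology with the batch artefact removed).
For risk modelling the pipeline uses `component = "fluct"`, i.e. $s_t$
alone: the filtered deviation from the patient's personalised, slowly
drifting baseline. This matches the stated intent of the original system —
the algorithm works on changes from personalised baselines — and matters
quantitatively: absolute values carry the between-patient baseline spread
(SD 0.3, as large as the pre-exacerbation shift itself), which a model
trained on one set of patients cannot transfer to new patients. In
end-to-end experiments on the synthetic cohort, absolute-value features
capped held-out discrimination around AUC 0.76–0.79 while
baseline-corrected features reach ≈ 0.85–0.89.

Parameter fitting in `run_pipeline()` defaults to one fit per marker
(applied to all patients of that marker) to bound runtime; per-series
fitting is available directly through `fit_dlm()`.

## Temporal features and labels

A "13-day window" spans 14 daily time points (anchor−13 … anchor): with the
three derivations per day — value, differential from the previous day, and
window-local integral — this yields the canonical 14 × 3 = 42 features per
marker. (13 time points would give 39, not 42, so the window must include
both endpoints.) Two boundary conventions were required: the first window
day's differential uses the day before the window when available and 0
otherwise, and the integral resets at the window start rather than
accumulating from study start, keeping the feature scale stationary across
a patient's record.

`label_time_to_exacerbation()` assigns each day the distance to the next
diagnosis day, with 200 — longer than any observation period — standing in
for "no event ahead". `build_database()` rolls windows one day at a time
and splits them: development = all windows anchored in the 13 days up to
each diagnosis plus a seeded random sample of stable windows (≥ 42 days
from any event; default 3 stable windows per exacerbation window, a ratio
the source design leaves unstated); production (blinded) = windows anchored
in the 6-week recovery span after each event plus every window from
patients with no events. Development and production are disjoint by
(patient, anchor) construction; windows 14–41 days before an event belong
to neither.

## The stepwise neural-network risk score

The risk model is a single-hidden-layer network: sigmoid hidden units,
skip-layer (direct input–output) connections, linear output predicting
time to exacerbation in days (capped at 200, regressed untransformed).
Inputs are standardised with constants computed on the training partition
only. Training uses `nnet`'s quasi-Newton optimiser with weight decay
(default 10⁻³ on standardised inputs and a unit-scaled target) — a
deliberate substitute for momentum gradient descent with epoch-level early
stopping, which the chosen optimiser does not expose; regularisation plays
the early-stopping role and the validation partition's error is recorded
in the selection trace.

`stepwise_select()` grows the input set one feature at a time under Monte
Carlo cross-validation with patient-stratified 60:20:20 splits (all windows
of a patient stay in one partition — the split unit was unstated in the
source design and window-level splits would leak heavily autocorrelated
windows across partitions). Two details proved essential:

1. **Warm starts.** Each candidate fit at step $k$ starts from the fitted
   weights of the chosen step-$(k{-}1)$ network, with the new input's
   connections initialised near zero. Cold restarts at every step make the
   optimiser increasingly unreliable as inputs accumulate — in our
   experiments the unseen-test error *rose* along cold paths while a
   regularised linear baseline on the same features did far better; warm
   paths descend monotonically and close most of that gap.
2. **Best-prefix selection.** The walk runs its full `max_steps` budget
   (default 20) and the selected panel is the path prefix with the lowest
   mean unseen-test MSE, implementing "panels selected by unseen-test
   performance" rather than stopping at the first non-improving step —
   with noisy per-step comparisons, first-failure stopping regularly
   truncates a path whose later prefixes are better.

`train_final()` tunes the hidden-layer size over a grid by mean unseen-test
MSE (warm-continuing fits at the selection's size; cold fits, with an
enlarged iteration budget, elsewhere), then polishes the winning network on
the full development set. The test partitions influence only which size and
prefix are *chosen*, never the gradient updates before that choice, and the
final evaluation in the acceptance suite is on entirely held-out patients.
`predict_risk()` is an explicit matrix forward pass on the stored weights;
`render_formula()` emits the same computation as a self-contained closed
formula, and `write_ann_json()`/`read_ann_json()` round-trip the model at
full double precision.

## Traffic lights and event-level evaluation

`classify_days()` maps a day's risk score to green if it exceeds the amber
cutoff and amber otherwise (scores exactly at the cutoff are amber, since
the green rule is strict), then marks a day red when at least 6 of the
trailing 7 days — counting amber *or red* days, so a red day cannot reset
its own run — are below the line. Red can therefore first fire on the 6th
day of an amber run, and a green-scored day immediately after a long amber
run can still be red; both behaviours are verified exhaustively over all
2¹⁴ amber/green patterns. Two cutoffs ship side by side because they play
different roles: `amber_cutoff` = 13.4 days (the decision-rule operating
point) and `roc_cutoff` = 21.19 days (the windowed-ROC operating point).
Both reference values are data-derived properties of the originally fitted
model and do not transfer to a model with a different output scale, so
`run_pipeline()` by default recalibrates the amber cutoff on the
development windows (Youden-optimal separation of 13-day pre-exacerbation
windows from the rest); `calibrate_cutoff = FALSE` restores the fixed
configured cutoff.

`evaluate_alarms()` uses the windowed definitions: a true event is a TP if
any red day falls in its 13-day window (a red run that starts before the
window still counts; lead time is measured from that run's first red day),
an FN otherwise; a maximal red run wholly outside all windows is one FP,
never one per day; TN is counted per stable day. The day-level TN
convention is reported in both forms — strictly green days (`tn_green`)
and non-red days (`tn_nonred`) — because published event arithmetic mixes
the two; `alarm_predictive_values()` exposes the bare PPV/NPV formulas for
working with printed counts. `recovery_status()` reports the fraction of
events back to non-red at day 14 after diagnosis.

## Shared statistics

AUC uses the rank (Mann–Whitney) formulation with ties counted one half,
exact against exhaustive pair enumeration; confidence intervals use a
seeded stratified bootstrap (2,000 resamples) rather than DeLong so a single
mechanism covers raw markers and model scores. Youden's J breaks ties
toward the lower cutoff. Per-marker screening p-values are unadjusted for
the multiplicity of the 35-marker screen by default, mirroring the original
analysis; callers can apply `p.adjust` to the returned column. Percentages
round to one decimal except where convention prints integers.

## Problem sizes in the test suite

The shipped tests exercise: filter-oracle equivalence on series of length
5–10; MCMC parameter recovery on twenty 360-day series (posterior means of
$V$, $W_s$, $\phi$ within 30% relative error on average); the decision-rule
truth table over all 16,384 length-14 patterns; null calibration of the
35-marker screen over 200 replicate cohorts of 55 patients (type-I ≈ 5%);
and an end-to-end run with 30 patients × 180 days × 5 markers in which the
pipeline trained on 20 patients separates 13-day pre-exacerbation windows
from stable windows on the 10 untouched patients with ROC AUC ≥ 0.8. These
sizes were chosen to make each property measurable with modest Monte Carlo
error while keeping the default test run fast.

## Known limitations

* The generator's MCAR missingness and additive log-normal noise are
  idealisations; the DLM's robustness to informative missingness is
  untested by design.
* Per-marker univariate DLMs ignore cross-marker correlation; a flare that
  moves all markers jointly is modelled only through each marker's own
  ramp.
* The stepwise search is greedy; it finds a good panel, not the optimum,
  and its path depends on the Monte Carlo split seeds (the panel-stability
  tally in the trace is the honest summary of that variability).
* Risk-score regression against time-to-exacerbation can only learn
  structure inside the biomarker lead-in; the apparent precision of
  predicted times far from events is an artefact of the 200-day cap.
* Event-level PPV is prevalence-sensitive: with rare events and thousands
  of stable days, even a specific rule yields many more called events than
  true ones, exactly as the published decision-rule arithmetic shows.
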