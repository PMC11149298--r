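---
title: "Methods: hourly KDIGO staging, the persistent-AKI endpoint, and the MAX-metric risk pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hourly KDIGO staging, the persistent-AKI endpoint, and the MAX-metric risk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paki3)
```

This vignette is the package's account of its methods: the model and its
assumptions, the tunable parameters and their defaults, the numerical
conventions, the design of the synthetic cohort generator, and the known
limitations. Everything stated here is computed by the package's own
functions and verified by its test suite; no empirical claim beyond that is
made.

## 1. The prediction problem

Among ICU patients who reach KDIGO AKI stage 2 or 3, we want an hourly risk
score for *persistent stage 3* (pAKI3): stage 3 sustained for at least 72
hours (`T72`), stage 3 for at least 48 hours ending in death (`D48`), or
renal replacement therapy initiated after more than 24 hours of stage 3
that was not itself an artifact of RRT (`RRT24`). Everything else that
reaches stage 2 is *transient*. The clinical pay-off of an early, reliable
pAKI3 alarm is triage: who is likely to need RRT and who will recover.

## 2. From raw events to an hourly grid

**Inputs.** A long event table — one row per `(stay, timestamp, variable,
value, unit)` over a 13-variable vocabulary plus `rrt` markers — and a
per-stay static table (demographics, admission/discharge/death times).

**Conventions.** Hour bins are half-open `[t, t+1)` anchored at admission;
a measurement at elapsed time τ belongs to bin `floor(τ)`. The grid spans
admission to the earlier of discharge and death. Duplicate
`(stay, time, variable)` rows keep the last-loaded value, so ingestion is
deterministic.

**Units and plausibility.** Values are converted to canonical units
(creatinine mg/dL, flow ml/kg/h, electrolytes mmol/L, …) via per-variable
conversion maps; rows with unknown units or values outside broad
physiologic limits are carried in a rejection ledger, never silently
dropped. The shipped limits and validity windows (`max_gap` = 24 h for
labs, 8 h for heart rate, 6 h for urine output) are package defaults — not
values taken from any particular registry — and are overridable through
`variable_specs()` / `read_variable_specs()`.

**Carry-forward.** A measurement is carried to hour `t` while its bin lies
in `(t − max_gap, t]`; beyond that the variable is missing. Two further
channels are kept per variable: staleness (hours since the last raw
measurement, unbounded) and a missingness flag.

**Urine volume → flow.** A recorded volume `V` at time τ with previous
record at τ′ is urine accumulated over `(τ′, τ]`, so it is spread uniformly
over those hour bins: flow `V/((τ−τ′)·weight)` ml/kg/h. Gaps longer than
`max_gap` credit only the trailing `max_gap` hours; intervening hours stay
missing. For integer-timed records this conserves volume exactly
(`Σ flow·weight = Σ V`), which the tests assert; for fractional timestamps
the attribution is per-bin and conservation is approximate.

## 3. Hourly KDIGO staging

**Baseline creatinine (bSCr).** Nadir-based: for stays with RRT, the
minimum creatinine between admission and first RRT initiation; otherwise
the minimum pooled over all of the patient's non-RRT stays. Stays with no
qualifying creatinine are excluded as unbaselinable.

**Creatinine bands.** With carried value `s` and ratio `r = s/bSCr`:
stage 1 if `r ≥ 1.5` or `s` rose ≥ 0.3 mg/dL above its trailing 48-h
minimum; stage 2 if `r ≥ 2`; stage 3 if `r ≥ 3`, or `s ≥ 4.0` mg/dL *with
an acute qualifier* (the 48-h rise, or `r ≥ 1.5`). The qualifier is our
interpretation of the absolute stage-3 criterion: without it, stable
chronic elevation at 4 mg/dL would be staged as acute injury. The 0.3
mg/dL rise criterion is switchable (`use_rise = FALSE`) since reasonable
implementations differ on it.

**Urine-output bands.** Trailing means of hourly flow: stage 1 if the 6-h
mean < 0.5 ml/kg/h; stage 2 if the 12-h mean < 0.5; stage 3 if the 24-h
mean < 0.3 or flow was zero across the entire trailing 12 h (anuria).
Oliguria bands require ≥ 80% coverage of their window (mean over observed
hours); anuria requires 100%. Coverage rules are a package choice — a
band whose window is mostly unobserved should not fire.

**Combination.** The hourly stage is the maximum of the two criteria,
forced to 3 under active RRT (initiation to end of stay; source registries
rarely record stops reliably). Hours where neither criterion is evaluable
carry stage 0 with `evaluable = FALSE`, distinguishable downstream. The
test suite proves the staging equal to an independent brute-force
re-evaluation of every hour from the raw events on 1,000 simulated stays.

## 4. Endpoint, exclusions, training labels

**Severe events.** Maximal runs of stage-3 hours. A run is truncated at
RRT initiation and its terminator recorded (`recovery`, `death`,
`discharge`, `rrt`). Hours that are stage 3 only because of the RRT
criterion never count toward event duration: the endpoint explicitly
discounts stage 3 "solely attributed" to RRT, and counting RRT-supported
hours would silently convert most RRT stays into 72-h events.

**Classification.** Events are scanned chronologically; the first event
satisfying a rule fixes the class and `T_p` (its first hour), with
precedence `T72 > D48 > RRT24` (the 72-h rule is the primary endpoint —
an 80-h event ending in death is `T72`, not `D48`). Later episodes are
ignored.

**Exclusions.** First-matching rule in a fixed category order, so every
excluded stay has exactly one reason:

1. *demographic* — age < 18, height outside 130–200 cm, renal transplant,
   missing sex/height/weight;
2. *staging* — < 24 h of data; no concomitant creatinine and urine-output
   measurement in the first 12 h; oliguria (without anuria) already
   present at the first evaluable urine-output hour (onset unobservable;
   anuric starts are kept); no hour at stage ≥ 2; no qualifying baseline;
3. *imminence* — death after < 48 h of stage 3; RRT after < 24 h (or
   none) of organic stage 3;
4. *ambiguity* — an event censored by end of data before its 72nd hour
   ("no measurement till the 72nd hour"). Because the stay grid ends at
   `min(discharge, death)`, death- and RRT-censoring are already caught by
   the imminence rules; discharge censoring is what remains here.

**Training labels.** Only stage ≥ 2 hours emit samples. Transient stays
contribute all such hours as negatives. Persistent stays contribute hours
in `[T_p − W, T_p + 12]` as positives; hours before `T_p − W` are dropped
(their outcome proximity is ambiguous) and nothing after `T_p + 12` is
ever scored. The pre-onset window `W` defaults to 48 h and is exposed in
`model_config(label_window = …)` rather than hidden — the right value is a
modelling choice, not a fact.

## 5. Features

Per sample hour, for each of the 13 variables: five statistics (mean, min,
max, std, last) over four trailing windows (6, 12, 24, 48 h) of

* the carried hourly series, and
* the *difference series* — consecutive differences of raw measurements,
  indexed by the later measurement's bin. Differencing raw measurements
  rather than carried values matters: carry-forward would fabricate runs
  of zero differences while a value is merely stale.

plus 13 staleness channels and 11 missingness flags (creatinine and urine
output excluded — their staleness already encodes absence). That is
`13·2·4·5 + 13 + 11 = 544` features, named deterministically
(`creatinine_diff_48h_mean`). Windows holding no observation yield missing
features; the tree learner routes missing values natively, so no
imputation is performed anywhere. Sample std uses denominator `n − 1` and
is missing for singleton windows; a constant window has std 0. Features
are causal by construction (windows are trailing; truncating a stay at a
urine-record boundary leaves earlier features unchanged, which the tests
assert).

All rolling statistics are computed in a few vectorized passes over the
cohort: stays are concatenated with 48 missing-hour pads (no window can
cross a stay boundary), means and sums via `data.table::froll*`, min/max
via a shift/pmax doubling scheme, "last in window" via a cumulative-index
trick.

## 6. Model and calibration

Gradient boosted trees (xgboost, `binary:logistic`, histogram method,
single thread for determinism). Defaults: 500 trees, depth 6, learning
rate 0.05, L1 penalty `alpha = 5` (a strong penalty that zeroes most
feature importances), positive-class weight = negative/positive sample
ratio. These are package defaults for the synthetic experiments, not a
claim about any published model's hyperparameters.

The cohort is split at the stay level, 70/30, grouped by patient (all
stays of a patient share a partition — otherwise a patient's physiology
leaks across the split) and stratified by endpoint class; classes with
fewer than two patients merge into a single persistent stratum with a
warning.

**Threshold.** The cutoff is the largest value whose per-stay MAX-metric
sensitivity on the calibration (validation) cohort reaches the 80% target,
under the strict-exceedance alarm rule (`max > cutoff`). Numerically we
scan candidates `m − 10⁻⁹` for every observed per-stay maximum `m`, i.e.
the supremum is approached from below with a fixed 10⁻⁹ tie-break margin;
an exhaustive-scan oracle in the tests confirms the selection. Once
calibrated the cutoff is frozen: applying the fit to a new cohort never
recalibrates.

## 7. Evaluation

**MAX metric.** Per stay, the maximum score over admissible samples
(persistent stays truncated at `T_p + 12`, which penalizes late alarms;
transient stays whole). Predicted persistent iff that maximum strictly
exceeds the cutoff. Lead time is `T_p` minus the first above-cutoff hour;
alarms landing in `(T_p, T_p + 12]` are counted as detections with
negative lead time and reported as such, not discarded.

**Curves.** auROC by trapezoid over the ROC of the per-stay maxima (equal
to the pairwise ranking probability with ties counted ½ — asserted against
brute-force enumeration and against pROC). auPR by the precision–recall
step curve without interpolation, the standard choice for rare endpoints.
Intervals are stay-level percentile bootstrap, default 1,000 resamples at
2.5/97.5%; both the resample count and the percentile levels are
configurable, since reasonable reports differ on the interval convention.

**Standardized predictive values.** `PPV(p) = sens·p / (sens·p +
(1−spec)(1−p))` and the analogous NPV, used both to re-express precision
at a 10% reference prevalence and as an internal consistency identity: at
the empirical prevalence they must equal the count-based PPV/NPV exactly.

**Fairness.** Average Odds Difference of each monitored subgroup against
the rest of the cohort; `|AOD| ≤ 0.1` flagged fair, groups lacking a
positive or negative stay flagged unreliable (their rates are not
estimable in any meaningful sense).

## 8. The synthetic cohort generator

The generator exists so that every pipeline stage is testable end to end.
It emulates exactly the statistical structure the pipeline reads:

* per-patient baseline creatinine (0.5–1.3 mg/dL); baseline-phase draws
  confined to `[0.95, 1.12]·b` so the realized nadir is controlled;
* a severe excursion in *every* stay: a stage-1/2 ramp (18–30 h), an onset
  measurement crossing 3× baseline at the planted hour, a plateau clamped
  ≥ 3.45·b (≥ 3× the largest possible nadir), and, for transient and
  `T72` stays, a measured recovery. Class is realized purely by run
  structure: transient plateaus last 14–40 h; `T72` ≥ 80 h; `D48` holds
  until death exactly 48 h after onset; `RRT24` gets RRT at onset + 25 h
  (the rule requires *more* than 24);
* urine output as irregular volume records (1–4 h apart) from a latent
  hourly flow, with volumes accumulating across dropped recordings — the
  volume-to-flow conversion is genuinely exercised; benign oliguric
  episodes (~0.4–0.48 ml/kg/h for 12–18 h) occur with probability 0.3 in
  every class, exercising the urine staging bands without creating
  stage 3;
* 11 ancillary variables on realistic scales with per-draw missingness
  (default 0.1; a sparse preset at 0.4 stresses robustness);
* a small fraction of two-stay patients, exercising the cross-stay
  baseline nadir rule.

**Signal.** Class-correlated structure is controlled by a single
`signal_strength` knob: persistent stays get pre-onset ancillary drift
(starting 48 h before onset), a pre-onset urine-flow decline, and a
slightly higher plateau, all proportional to the knob. At
`signal_strength = 0` these vanish and everything observable up to
`T_p + 12` is exchangeable between classes by construction — the reason
*every* stay, transient included, carries a full stage-3 excursion. This
gives a clean null: a model trained on zero-signal cohorts should sit at
auROC ≈ 0.5, and the test suite asserts its bootstrap interval covers 0.5.
At the default `signal_strength = 1` the endpoint is nearly separable;
learnability is monotone in the knob.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: physiologic feedback and treatment
response, correlated multivariate dynamics, informative (outcome-dependent)
missingness, measurement artifacts, true baseline-creatinine uncertainty,
or realistic class geometry near the decision boundary. Performance
numbers on synthetic cohorts characterize the pipeline's correctness and
calibration machinery, not expected clinical discrimination.

**Problem sizes.** The shipped experiments use 2,000-stay cohorts at 10%
persistent incidence across three seeds for the end-to-end learnability
and calibration checks, 1,000 stays for the staging-oracle equivalence,
and 800 stays for the null run — sizes chosen to make the stochastic
checks stable while keeping the default test run quick.

## 9. Numerical choices and degenerate inputs

* Hour bins half-open, measurements at admission fall in bin 0.
* Calibration tie-break margin 10⁻⁹ below observed maxima; alarm rule is
  strictly greater-than everywhere.
* The fairness band check allows 10⁻¹² slack so exact-boundary AODs
  (±0.1) are fair.
* Stays with no events resample to an all-missing grid; empty severe-event
  sets classify as transient; one-class evaluation sets, unreachable
  sensitivity targets, non-positive weights and baselines are errors, not
  silent results.
* Seeds: every stochastic component (generator, split, learner, bootstrap)
  is driven by an explicit seed and restores the caller's RNG state.

## 10. Limitations

The 544-feature layout is a faithful but configurable reconstruction — the
exact composition of such vectors is never fully published, so the layout
is treated as a default, not a contract. The boosted-tree hyperparameters
are package defaults. The 0.3 mg/dL rise rule, the acute qualifier on the
4.0 mg/dL criterion, the urine-band coverage thresholds, the pre-onset
labeling window and the oliguria-at-start operationalization are all
documented interpretations, deliberately exposed as configuration rather
than baked in. Real-data validation requires access to clinical registries
and is outside the package's scope.
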