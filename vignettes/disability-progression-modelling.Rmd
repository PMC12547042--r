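---
title: "Estimating EDSS classes and forecasting disability progression from administrative data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating EDSS classes and forecasting disability progression from administrative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Disability in multiple sclerosis (MS) is measured with the Expanded
Disability Status Scale (EDSS, 0–10 in 0.5 steps), which requires a
neurological examination and therefore lives in clinical records, not in
the administrative databases that cover whole populations.  `edssprog`
implements a two-model strategy for bridging that gap:

1. **EDSS class estimation.**  A feed-forward softmax network maps
   healthcare-utilization features, aggregated over a patient's first six
   months of observation, to one of three collapsed EDSS classes — C1
   (EDSS ≤ 3.0, mild), C2 (3.5–5.5, moderate), C3 (≥ 6.0, severe,
   ambulatory aid required).  It is trained on the subset of patients whose
   administrative records can be linked to a clinical registry carrying
   true EDSS scores, and then applied to the whole population.
2. **Progression forecasting.**  A feed-forward risk network `g(x)` is
   trained with the negative log Cox partial likelihood, so `exp(g(x))` is
   a relative hazard for the transition to a higher EDSS class.  Combined
   with a Breslow baseline cumulative hazard `H0(t)`, it yields absolute
   cumulative hazards `H(t|x) = H0(t) exp(g(x))` and survival probabilities
   `S = exp(−H)` at any horizon — in particular the 5-year (60-month)
   cumulative hazard used for risk stratification.

Downstream, patients are stratified into low / moderate / high risk by
1-D k-means on `H(60|x)` (the high-risk threshold is the smallest hazard in
the top cluster), and population flows between classes over the horizon are
projected into a Sankey-ready transition table.

Because the kind of regional registry this pipeline targets cannot be
shipped, the package includes a first-class synthetic-registry generator
whose outputs exercise every stage; all tests and the acceptance script run
on synthetic data only.

## The data model

Four linked tables keyed by an anonymised patient id (deterministic
linkage): drug prescriptions (`patient_id, date, drug_name`), hospital
discharges (`patient_id, admit_date, discharge_date, icd9_codes,
emergency_flag`), outpatient encounters (`patient_id, date,
service_category`), demographics (`patient_id, sex, birth_year,
resident_flag`); plus a clinical table of dated EDSS scores with relapse
flags for a sub-cohort.

**Case-finding** requires at least one MS record: an MS-specific DMT
prescription, an admission listing ICD-9-CM 340 among the discharge
diagnoses (primary or secondary), or an outpatient encounter in a
configurable MS-specific service list (default: consultation and
rehabilitation; laboratory work is deliberately not disease-specific).
The entry date is the earliest qualifying record.  Non-residents and
patients with missing sex or birth year are excluded, with a per-reason
report.

**Features** are aggregated over the half-open window
`[entry, entry + 6 calendar months)` (month arithmetic clamps the day of
month, e.g. Aug 31 + 6 months → Feb 28/29): DMT counts by route class
(monoclonal antibody / oral / injectable) and efficacy tier (platform /
high-efficacy), days on therapy (30-day supply per prescription, overlaps
merged, clipped to the window), a platform→high-efficacy switch indicator,
admission counts (total / ICD-9 340 / emergency) and total length of stay,
outpatient counts in six service categories, a severe-disability
discharge-code flag, age (window-start year minus birth year — day-level
birth dates are not assumed in administrative extracts) and sex.
"Duration of therapy" is within-window days covered, not cumulative time
since first DMT; that reading is an assumption and is configurable only by
editing the feature builder.

**Labels** attach the relapse-free clinical EDSS assessment nearest to the
window end (ties → the earlier assessment).  Relapse-associated scores are
filtered because they transiently inflate the EDSS.

**Survival samples** (time to class transition) also come from the
clinical registry: the baseline class is the relapse-free assessment
nearest entry; the event is the first relapse-free assessment in a higher
class, timed at the midpoint between it and the previous assessment
(transitions happen between visits; using the visit date itself would
systematically inflate times by about half the visit interval).  Patients
without an observed transition are censored at their last relapse-free
assessment.  Patients already in C3 at baseline are excluded — the top
class is absorbing.

## The two networks

Both networks are plain dense ReLU networks trained with Adam, implemented
directly in R; at these sizes (tens of units, a few thousand rows) there
is nothing for a deep-learning framework to add.

**Classifier** (`classifier_config()`): hidden layers 64 and 32, softmax
output over three classes, categorical cross-entropy (implied by the
softmax output), learning rate 0.001, batch size 32, dropout 0.2 on hidden
activations (inverted dropout, inactive at prediction time), L2 strength
1e-4 on weights (a value had to be chosen; 1e-4 is a conventional mild
penalty), stratified 70/30 train/validation split, features standardized
with training-split statistics only.  The default 10 epochs suit cohorts
of a couple of thousand labelled patients; `run_pipeline()` uses 60 epochs
because on the few-hundred-patient labelled subsets of the synthetic
registry the training loss has not plateaued at 10.  No class re-weighting
is applied.  `grid_search()` evaluates the full Cartesian grid over
learning rate, batch size and hidden widths on the validation split, with
ties broken toward the earliest grid row; the default grid in examples
(lr ∈ {1e-2, 1e-3, 1e-4}, batch ∈ {16, 32, 64}, width1 ∈ {32, 64, 128}) is
a convention, not a canonical set.

**Risk network** (`survival_config()`): hidden layers 32, 32, 16, a linear
1-unit score output, full-batch Adam on the Breslow-tie partial
likelihood.  Full-batch is deliberate: Cox risk sets are global, and
mini-batch partial likelihoods are biased.  Early stopping monitors the
per-event validation loss with tolerance 1e-4 and patience 10, restoring
the best weights.  Evaluation is 5-fold cross-validation reconciled with a
60/20/20 split: each fold's 20% is the test subset and the remaining 80%
is split 3:1 into training and validation; the final model is refit on all
data (the "training + validation portion"), with an internal stratified
80/20 split for early stopping, and the Breslow baseline is estimated from
the final fit's scores on the full sample.  `hidden_sizes = integer(0)`
degenerates to a classical linear Cox model fitted by gradient ascent,
which the tests use for coefficient-recovery checks against
`survival::coxph`.

Ties are handled with the Breslow convention in both the loss and the
baseline-hazard estimator so that the training objective and the estimator
are consistent; with all scores equal the baseline reduces to
Nelson–Aalen.  A single "transition to any higher class" event is
modelled, not one model per ordered transition: with three classes and an
absorbing top class the distinction only matters for C1→C3 jumps within
one visit interval, which the generator cannot produce and real 6-monthly
follow-up rarely shows.

## Metrics

`classification_report()` reports accuracy, macro-averaged precision /
recall / F1 (per-class values are also emitted, so a weighted reading can
be reconstructed), per-class sensitivity and specificity, and 95%
percentile bootstrap confidence intervals (default 1000 patient-level
resamples; the CI method is a convention — nothing in the metric forces
bootstrap).  `concordance_index()` is Harrell's C over pairs whose earlier
time is an event, with half credit for tied risks; no truncation
adjustment is applied.  `integrated_brier_score()` uses inverse
probability-of-censoring weights from the Kaplan–Meier estimate of the
censoring distribution and a trapezoid average over a grid defaulting to
100 points spanning the observed event times; subjects whose required
censoring weight is zero are dropped with a warning.  `kaplan_meier()` is
the product-limit estimator with right-continuous evaluation.

## Risk stratification and projection

`kmeans_1d()` wraps `stats::kmeans` with 10 seeded random restarts plus a
deterministic quantile start, keeping the best within-cluster sum of
squares; in one dimension the optimal clusters are contiguous, and the
tests verify equality with an exhaustive contiguous-partition search.  The
high-risk threshold is the minimum hazard in the top cluster — a value
attained by a real patient, rather than a midpoint between clusters.

`project_transitions()` supports two readings of how per-patient 5-year
hazards become population flows, because the dichotomous "high-risk"
threshold alone cannot produce fractional flows:

* `mode = "expected"` (default): each patient below C3 moves to the
  adjacent higher class with probability `p5 = 1 − exp(−H5)` and stays
  otherwise; flows are expected population fractions.
* `mode = "threshold"`: patients move exactly when `H5` reaches the
  high-risk threshold.

Both restrict moves to the adjacent class within the horizon and keep C3
absorbing.  The table conserves mass to 1e-9 and contains no downward
flows by construction.  Projection uses a closed cohort (patients entered
by the projection year); the current class of every patient, labelled or
not, is the classifier's prediction on the projection-year window, so the
projection covers the whole population rather than the linked subset.

## The synthetic registry

`sim_config()` defaults encode the study conditions the pipeline is
designed for: ~64% female, age 42.5 (SD 13.5, truncated to 18–85 with the
parent mean adjusted so the realized mean is 42.5), entry class mix
9/62/29, clinical EDSS linkage for 22% of case-findable patients,
assessments every ~6 months, 8% of assessments relapse-flagged, 3%
non-residents, 5% missing demographics, 2% of patients with no records.

Progression is a per-patient homogeneous Poisson process over adjacent
class transitions with monthly hazard `0.006 · exp(0.4·age_z − 0.3·female)`
and C3 absorbing.  Exponential waiting times make the proportional-hazards
model correctly specified (so a linear fit can recover the generator's
coefficients in expectation) and give closed-form five-year progression
probabilities `1 − exp(−60·rate)`, from which `true_transition_table()`
builds the analytic benchmark used by the pipeline-level tests.  The
0.006/month baseline keeps the population mix quasi-stable over a
seven-year study (as population surveillance of a slowly progressing
disease shows) while still producing roughly 150 observed transitions per
5000 simulated patients — enough to fit the risk network.

Utilization intensities are drawn per 6-month period from the latent class
at the period start.  Every class-dependent intensity scales with
`signal_strength`; at 0 the three classes are statistically identical, so
a classifier can only perform at chance — the null-signal tests rely on
this.  At the default signal the classes are strongly separated
(rehabilitation encounters ≈ 0.1 / 9 / 18 per period; severe-disability
discharge codes on 1% / 35% / 90% of admissions; graded admission rates,
lengths of stay, consultations, and high-efficacy DMT use), putting the
classifier around 0.9 held-out accuracy.  That is deliberately an
easier regime than real administrative data, where EDSS estimation
accuracies near 0.7 are typical: the synthetic tests verify that the
machinery is correct, not that real claims data carry this much signal.

What the generator does **not** emulate: relapsing–remitting EDSS
fluctuation (scores within a class are drawn independently per visit, and
classes never decrease), drug-level pharmacoepidemiology (drugs are drawn
i.i.d. given the tier, so within-window "switches" are noisy), regional
geography, seasonality, coding errors, and any dependence of the
progression hazard on treatment.  Passing tests therefore demonstrate
correctness of the estimation machinery under a favourable, well-specified
data-generating process — not clinical validity on real claims.

All randomness flows from `seed`, with sub-streams `seed`, `seed+1`,
`seed+2` for population, utilization and clinical tables, so a table can
be regenerated alone and identical configurations reproduce every output
byte-for-byte.

## Numerical choices and degenerate inputs

* Cox loss and gradient shift scores by their maximum before
  exponentiating; the shift cancels exactly in `g − log Σ exp`.
* Zero events make the partial likelihood undefined: an error, not a
  zero.  Folds without events are rejected with a pointer to
  event-stratified folds (which the trainer already uses).
* A horizon beyond the last observed time evaluates the last Breslow step
  and warns.
* Standard deviations of constant features are replaced by 1 in the
  scaler, leaving the feature centred at zero rather than dividing by 0.
* Uncatalogued drugs are counted in an explicit `n_dmt_other` bucket with
  a warning — newer DMTs (e.g. agents entering the market after a study
  window) must not silently vanish.
* `stats::kmeans` interprets a length-1 centers argument as a cluster
  count, so `k = 1` is short-circuited to the exact answer (the mean).

## Problem sizes

The shipped tests run the complete pipeline at 5000 patients (roughly 4500
included after exclusions, 950 clinically labelled, 700 survival samples
with ~150 events), which finishes in well under a minute on a single CPU;
unit tests use 300–3000 patients.  Oracle-recovery checks use n = 2000
proportional-hazards simulations, the scale at which the partial-likelihood
optimum is tight enough to separate implementation error from Monte Carlo
noise.  These sizes were chosen to make sampling error small relative to
the tested tolerances.

## Known limitations

* On weak-signal, small-n survival data the MLP risk network discriminates
  worse than a classical Cox fit on the same rows (in the synthetic
  pipeline, fold C-index ≈ 0.55 against a coxph ceiling of ≈ 0.63): with
  only ~400 training rows and 21 mostly-irrelevant features, early
  stopping on a noisy validation loss halts before the small true signal
  is isolated.  This mirrors the general experience that neural survival
  models need either strong signal or much more data to beat the linear
  model; the high-signal tests show the same network matching the oracle.
* Class-transition projection ignores calendar-time changes in treatment
  mix and hazard over the projection window.
* The classifier's argmax class shares inherit a small prior-shift bias
  when the population class mix drifts far from the training mix; at the
  default generator signal this bias stays within the tested tolerances.
* Probability calibration of the softmax outputs is not performed, and no
  ordinal structure is imposed on the three classes.
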