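---
title: "Modelling the stroke thrombolysis pathway: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the stroke thrombolysis pathway: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Intravenous thrombolysis is an effective treatment for acute ischaemic
stroke when given soon after onset, yet its use varies several-fold between
hospitals admitting emergency stroke patients.  That variation has two
broad sources: *process* (how quickly a patient moves from onset to
arrival, brain scan, and needle, and whether an onset time can be
established at all) and *decision-making* (which scanned, in-time patients
a hospital's clinicians choose to treat).  This package separates the two,
per hospital, with a Monte Carlo model of the pathway and a
machine-learning model of the treatment decision, then asks "what if?"
questions: what happens to a hospital's thrombolysis use and to the
expected number of good outcomes if its pathway were faster, if it
established onset times more often, or if its decisions matched those of a
benchmark group of more liberal hospitals?

Because the patient-level national audit extract that motivates this design
is restricted, the package ships a synthetic-data generator that emulates
the statistical structure of such data.  Every stage of the pipeline —
fitting, learning, simulating, reporting — runs against generated records
with a known ground truth, which is what makes the whole pipeline testable.

# The pathway model

Each virtual patient passes through the gates of a simplified hyperacute
pathway and leaves at the first failure:

1. **Onset known** — Bernoulli with the hospital's onset-known proportion.
2. **Scanned in time** — onset-to-arrival and arrival-to-scan times are
   drawn from the hospital's fitted lognormal distributions; the patient
   continues only if scanned (probability `p_scanned`, 1 in the base
   scenario) and onset-to-scan is within the eligibility window.
3. **Decision** — Bernoulli with the hospital's likelihood to treat a
   patient scanned in time (`p_treat_eligible`).
4. **Time to treat** — the patient must still be treatable: at least
   `min_remaining` minutes left before the treatment window closes at scan
   completion, and onset-to-needle (adding a lognormal scan-to-needle time)
   within the treatment window.

Survivors are treated at their onset-to-needle time.  The defaults are an
eligibility window of 240 minutes onset-to-scan, a treatment window of 270
minutes onset-to-needle (the 4.5-hour licence), and 15 minutes minimum
remaining time.  The exact limits at each gate are declared package
defaults, not assertions about any particular audit's processing rules; all
three are configurable in `sim_config()`.

A run pushes `N_adm × years_per_hospital` patients through each hospital —
100 years of admissions per hospital by default, which keeps hospital-level
Monte Carlo noise well below the between-hospital differences of interest.
Scan-to-needle times are drawn for all virtual patients, treated or not;
the unused draws are harmless and keep the simulation fully vectorised.

**Random-number streams.** Every hospital has its own sub-stream derived
from the base seed and the hospital id, so results are independent of how
many hospitals are simulated and in which order.  Scenario runs reuse the
hospital's stream, and all variates are drawn up front in a fixed order, so
two scenarios differing only in a parameter see the same patient-level
noise wherever their distributions agree (common random numbers, which both
reduces comparison variance and makes pathway-speed improvements pathwise
monotone).

# Fitting hospitals from patient records

`estimate_pathway_params()` reduces one hospital's admissions
(out-of-hospital-onset strokes only) to the simulator's parameter vector:

* `p_onset_known` — fraction of admissions with a determined onset time;
* `(mu, sigma)` per stage — lognormal fits over records where the stage
  time is defined (onset-to-arrival requires a known onset; arrival-to-scan
  a scan; scan-to-needle is observed only for treated patients);
* `p_treat_eligible` — treated patients divided by patients *scanned within
  4 hours of known onset*, i.e. onset-to-scan ≤ 240 minutes, not
  arrival-to-scan ≤ 240;
* `p_scan4h_arrival` — fraction scanned within 4 hours of arrival, among
  all arrivals.

The lognormal family is a deliberate modelling choice: stage times are
right-skewed and positive, the family is the standard process-time model in
this setting, and it makes the fit exactly identifiable from two log-scale
moments.  Numerical conventions, chosen so documented examples are exact:

* times ≤ 0 are clamped to 1 minute before the log transform (avoids
  `-Inf`; recorded times are integer minutes ≥ 1 anyway);
* `sigma` is the *population* standard deviation of log-times (divisor
  `n`), so samples `exp(1), exp(3)` give exactly `(2, 1)`;
* fewer than two usable times for a stage is an error naming the hospital
  and stage, not a silent fallback;
* a zero denominator for `p_treat_eligible` yields an explicit zero with a
  warning;
* the national upper quartile of `p_onset_known` is unweighted across
  hospitals (each hospital counts equally, whatever its size) with the
  standard linear-interpolation quantile (type 7), so values
  `0.2, 0.4, 0.6, 0.8` give 0.65.

# Decision models and the benchmark

A probability random forest (100 trees, unrestricted depth, fixed seed,
single thread) is trained per hospital on its patients arriving within 4
hours of known onset, predicting whether thrombolysis was given from:
stroke severity (NIHSS), age band, onset-time precision, anticoagulant use,
pre-stroke dependency (mRS), onset-to-arrival and arrival-to-scan times,
arrival mode, and stroke type.  No feature that directly encodes the
outcome (such as a reason for withholding treatment) is present in the
schema.  The forest hyperparameters are fixed rather than tuned: the model
family is chosen for per-hospital independence and explainability, and the
pipeline's conclusions should not hinge on a tuning loop.  Hospitals with
fewer than 25 eligible training patients are refused; a hospital whose
eligible patients are all treated or all untreated gets an explicit
constant model.

Accuracy is reported by stratified 5-fold cross-validation (5 is the
conventional default; the fold count is a parameter).  Three metrics are
computed per fold and averaged: proportion correct at a 0.5 threshold, ROC
area under the curve (the Mann-Whitney rank statistic), and the value at
which sensitivity and specificity cross as the classification threshold is
swept, interpolating linearly between the adjacent thresholds that bracket
the crossing.

The benchmark construction mirrors the audit-scale procedure at whatever
scale the data allow: a fixed fraction (20%) of each hospital's eligible
patients is held out before any training; a shared cohort is sampled from
the pooled holdout (so it is disjoint from every training set by
construction, not by bookkeeping); every hospital's model scores the same
cohort; and the hospitals with the highest predicted cohort treatment rates
— 30 by default — form the benchmark set.  Rate ties are broken by
hospital id so membership is reproducible and independent of model order.
A patient "would be treated by the benchmark" when strictly more than half
of the member models say so; an exact tie counts as *no* (the conservative
reading — the procedure's description does not fix the tie rule).

`benchmark_rate()` scores a hospital's *treatment-eligible* patients
(scanned within 4 hours of known onset) against this vote.  The denominator
deliberately matches `p_treat_eligible`, so the Benchmark scenario can
substitute one for the other without changing populations mid-formula.

# Outcomes

The clinical endpoint is the probability of an excellent recovery (mRS 0-1
at 3-6 months), per age group (under 80 / 80+).  Untreated patients get the
age group's baseline probability `p0`.  For treated patients the log-odds
of a good outcome decline linearly with onset-to-needle time from
`qlogis(p_t0)` at time zero to `qlogis(p0)` at the time of no effect
`t_ne`; later treatment reverts to baseline (no harm is modelled, and
neither are haemorrhagic complications — the model is a benefit ceiling,
not a risk-benefit calculus).  Hospital benefit is the *expected* excess of
good outcomes — probabilities summed over treated patients, never sampled —
scaled per 1000 admissions, so the reported benefit carries no outcome-level
Monte Carlo noise.

The shipped coefficients (`p0` = 0.20/0.07, `p_t0` = 0.33/0.14, `t_ne` =
378 minutes for under-80/80+) are illustrative placeholders with the right
clinical shape: benefit that roughly halves over the licence window and
vanishes around 6.3 hours, and smaller absolute probabilities at older
ages.  They are deliberately configuration, not constants: a study applying
this model should load its own published coefficient set via
`read_outcome_params()`, and comparisons of benefit *levels* against
external reports are only meaningful with matching coefficients.
Differences and orderings between scenarios are much less sensitive to the
exact values, which is what the package's own tests rely on.

# Scenarios

Three transforms of the fitted parameter vector, alone or combined:

* **Speed** — 95% of patients scanned, arrival-to-scan fixed at 15
  minutes, scan-to-needle fixed at 15 minutes; the remaining 5% are *not
  scanned within 4 hours of arrival* and leave at the scan gate.  The 5%
  are implemented as exclusion at the gate rather than as a long sampled
  time: it matches the stated wording of the change and avoids inventing a
  tail distribution for never-scanned patients.
* **Onset-known** — `p_onset_known` raised to the national upper quartile
  where currently lower; hospitals already above keep their own value.
* **Benchmark** — `p_treat_eligible` replaced by the benchmark majority-
  vote rate on the hospital's own patients, whatever direction that moves
  it.

Each transform touches only its own fields, is idempotent, and commutes
with the others, so combined scenarios are order-independent.  The
benchmark rate is computed once, on each hospital's base-scenario eligible
population.  In principle the onset-known change enlarges the eligible
population and could shift its case mix; under this generator the patient
features that drive the vote are independent of whether onset is known
(only the precision flag is linked), so the base-population rate is also
the correct rate for the enlarged population, and recomputing it per
scenario would only add noise.  With real data this independence is an
assumption, and a benchmark rate per scenario population would be the
conservative alternative.

National summaries weight hospitals by admission volume.  Reported
percentages are rounded to one decimal place in the output tables; all
internal computation is unrounded.

# The synthetic generator

`generate_hospitals()` and `generate_patients()` emulate the statistical
skeleton of a national stroke audit:

* ~132 hospitals × 3 years, 350-900 admissions per hospital-year;
* onset-known proportions Beta-distributed with mean 2/3;
* lognormal stage times with per-hospital parameters drawn from uniform
  priors (onset-to-arrival median ≈ 3 hours, arrival-to-scan median ≈ 20-60
  minutes, scan-to-needle median ≈ 20-35 minutes);
* a ground-truth treatment decision that is logistic in patient features —
  concave in NIHSS (propensity peaking at NIHSS 12, so very mild and very
  severe strokes are treated less), higher with a precise onset time, lower
  with age 80+, anticoagulation, pre-stroke dependency and late arrival —
  plus a hospital intercept with SD 1.45 log-odds;
* hard eligibility gates identical to the simulator's: only ischaemic
  strokes with known onset, scanned within 240 minutes of onset and
  treatable within 270 minutes, can be treated;
* a latent "organisational quality" axis (Gaussian copula, loading 0.55)
  that correlates scan speed, onset ascertainment and willingness to
  treat while preserving each trait's marginal distribution.

The defaults were calibrated once, before the test expectations were
frozen, against the conditions the generator is meant to emulate: pooled
national use close to 11.6% of admissions, roughly 37% of patients arriving
within 4 hours of known onset, about two thirds of onset times determined,
and hospital-level rates spanning at least 5-25% (a roughly five-fold
spread).  The quality axis is what makes the upper tail reachable: with
fully independent hospital traits, no hospital is simultaneously fast and
liberal enough to exceed ~23% use.  The steepness of the decision
coefficients was likewise set so that the planted rule is learnable at
roughly the accuracy scale reported for real per-hospital models (low-to-
mid 80s percent with ~500 training cases) — a much flatter rule would make
every hospital's decisions look like coin flips, which real decisions are
not.

Schema realism the generator does include: missing values as empty fields
(never zero) for onset-to-arrival when onset is unknown, arrival-to-scan
for the ~2% never scanned, and scan-to-needle for untreated patients;
in-hospital-onset strokes (~5%) that are generated but flagged, and
excluded by every downstream filter; and filler fields (arrival mode)
uncorrelated with anything.

What it does *not* emulate — and therefore what passing tests do and do not
show: the joint distribution of NIHSS, age and onset ascertainment in real
admissions (the synthetic marginals are plausible but invented); the full
62-feature audit schema; within-hospital temporal drift; clinicians
reacting to the remaining licence time when deciding (the generator's rule
uses onset-to-arrival but not scan-to-needle); and any resource contention
(no scanner queues or staffing constraints, which the pathway model itself
also omits).  Tests passing on this generator demonstrate that the
*pipeline machinery* — fitting, learning, benchmarking, simulation,
aggregation — is correct and internally consistent, not that any particular
national estimate transfers to real data.

`ground_truth_rate()` is a deliberate second implementation of the same
patient model as an explicit scalar loop, kept free of the vectorised code
paths, so that generator and simulator can each be checked against an
independent oracle.

# Problem sizes and tolerances in the test suite

The suite exercises the pipeline at sizes chosen to keep statistical
tolerances meaningful: oracle-equivalence comparisons run 100 000 virtual
patients per hospital and accept differences within 3 standard errors of
the difference of two binomial estimates; parameter recovery uses 10 000
admissions and a 0.05 absolute tolerance on lognormal parameters;
fit-then-simulate fidelity uses a 20-hospital system at 600 admissions/year
and requires the mean absolute difference between simulated and realised
use to stay under 1 percentage point; the benchmark-recovery check plants
30 clearly liberal hospitals among 60 and requires at least 25 to be
re-identified from a 5000-patient shared cohort.  All stochastic tests run
under fixed seeds.

# Known limitations

* The treatment-likelihood estimate absorbs everything downstream of the
  scan gate (including the few decided-for patients who run out the
  treatment window), and the simulator applies its window exit again; the
  double-counting is small because scan-to-needle distributions are fitted
  from treated patients, but it is one reason simulated use sits a few
  tenths of a percentage point below observed use on average.
* Outcome coefficients are placeholders (see above); benefit levels are
  comparable only within a configuration.
* The benchmark vote inherits every bias of the per-hospital forests; with
  fewer than ~125 eligible patients a hospital's model, and therefore its
  vote, is unreliable, and the training refusal threshold (25) is a floor,
  not a sufficiency guarantee.
* Scenario projections assume pathway changes leave case mix unchanged —
  the same assumption the what-if framing makes explicit.
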