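---
title: "Conformal prediction of the MS disease course: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformal prediction of the MS disease course: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscourse)
```

## The problem

Multiple sclerosis usually begins as relapsing-remitting disease (RRMS) and
later converts to secondary progressive disease (SPMS). The conversion is
gradual and is diagnosed retrospectively, typically around three years after
it has actually happened, because a clinician must observe sustained
progression before changing the label. A per-visit classifier that
distinguishes the two courses from routinely collected electronic health
record data can flag progression earlier — but a bare point prediction is of
limited clinical value without a calibrated statement of its uncertainty.

`mscourse` implements this pipeline end to end: a synthetic registry-like
cohort generator with known ground truth, the cleaning and feature-derivation
rules for longitudinal visit data, probabilistic classifiers, a **Mondrian
inductive conformal predictor** wrapped around them, evaluation surfaces
(calibration and efficiency curves, confusion tables at a confidence),
per-patient disease-course trajectories with transition-time estimation, and
additive per-visit feature attributions.

## The conformal model

Given a fitted classifier with estimated class probabilities, the
nonconformity of a visit $x$ under a hypothesized label $c$ is

$$\alpha(x, c) = 1 - \hat P(c \mid x),$$

the standard choice for probabilistic classifiers. An inductive conformal
predictor computes nonconformity scores $\alpha_1, \dots, \alpha_n$ on a
calibration set disjoint (by patient) from the training set, and for a new
visit ranks its score among them with the test point counted as its own
$(n+1)$-th element:

$$p = \frac{\left|\{\, j = 1, \dots, n+1 : \alpha_j \ge \alpha_{n+1} \,\}\right|}{n + 1},$$

ties counted on the $\ge$ side. The prediction set at significance
$\varepsilon$ (confidence $1-\varepsilon$) contains every label with
$p \ge \varepsilon$: a single label, both labels (the model cannot separate
them — the clinically interesting "possible transition" signal), or the empty
set (the visit is unlike the calibration data under either label).

The **Mondrian** variant calibrates within each true class separately, so
the error guarantee holds per class rather than only on the population —
essential here because the two courses are imbalanced and per-patient
reliability is the point. Two consequences used throughout the tests:

* *validity*: for exchangeable data the per-class error rate at significance
  $\varepsilon$ is at most $\varepsilon$ in expectation;
* *nestedness*: sets shrink monotonically as $\varepsilon$ grows, so the
  multiple-label fraction is non-increasing and the empty fraction
  non-decreasing in $\varepsilon$.

Non-smoothed p-values (deterministic, conservative under ties) are the
default. A smoothed variant, which randomizes the tie mass and makes
true-label p-values exactly uniform, is available behind
`cp_pvalue(..., smoothed = TRUE)` for distributional checks.

Confidence is expressed in percent at every user surface
(`predict(icp, X, confidence = 93)`); significance is internal.

## What the simulator emulates

No public registry-scale dataset of this kind can be shipped, so the package
generates one with known ground truth. `sim_config()` defaults describe the
study conditions:

* three archetypes at 68% / 19% / 13% (RRMS-throughout, SPMS-throughout,
  transitioning), the composition reported for registry test splits;
* a latent transition drawn with a discrete hazard increasing in age and
  disease duration, so progressive patients are older with longer disease —
  SPMS-throughout patients enter follow-up late (about a decade and a half
  after onset), reproducing the duration and disability margins of real
  cohorts;
* EDSS with relapse-spike-and-partial-recovery dynamics in RRMS
  (spike 1.5 points, 80% recovery) and a progressive drift in SPMS
  (0.45 points/year initially) that **saturates** toward a ceiling of 4.5
  accumulated points: the EDSS scale is bounded and progression decelerates
  at high scores; without saturation a 20-year progressive course would
  leave the scale;
* relapse rates of 0.45/year (RRMS) vs 0.12/year (SPMS), SDMT decline, MRI
  lesion counts with more gadolinium-enhancing activity during RRMS, MSIS-29
  subscales tracking disability;
* gamma-jittered visit intervals (mean 9 months), per-stream missingness
  (SDMT 50%, MRI 60%, MSIS 50% of visits unmeasured);
* a clinician labelling delay, truncated-normal with mean 3 years and SD 1,
  applied **to the recorded course label only** — disease dynamics follow
  the true state. This is what lets the package reproduce the
  model-earlier-than-registry discrepancy rather than assuming it.

`class_separation` scales every state-dependent difference around its
between-state average: 0 makes the two states dynamically identical (used to
test the null), 1 is the nominal difference, larger values approach a
noiseless limit (used for parameter-recovery tests).

What the simulator does *not* emulate: real registries have heterogeneous
clinician behaviour, informative visit scheduling, measurement error
correlated across streams, treatment effects on dynamics, and mortality.
Passing tests on this generator demonstrate that the machinery is correct
and that the conformal guarantees hold under the stated conditions — they do
not certify performance numbers on real registry data.

## Feature pipeline

The derivation rules follow registry practice for longitudinal EHR data:

* visits missing EDSS or a course label are dropped, as are patients missing
  birth or debut dates (`clean_cohort()`, with a counted removal report);
* for patients recorded RRMS throughout, all visits within two years of
  their last visit are removed (`prune_rrms_tail()`): their endpoint is
  undetermined — an unrecorded transition may already have begun. The
  anchoring last visit itself is removed too, since its endpoint is exactly
  as undetermined; the report logs the removals so the alternative
  convention is auditable;
* each visit carries the most recent prior-or-same-day observation of every
  stream together with the patient's age at that measurement
  (`carry_forward_features()`); streams never observed are encoded −1, the
  single missingness marker throughout;
* relapses are cumulated per category up to and including the visit day;
  lesion counts are binned (≤9 → 1, 10–20 → 2, >20 → 3); drugs map to
  treatment categories through an editable lookup shipped with the package;
* ages are computed as days/365.25 and reported at 0.1-year resolution, a
  fixed convention chosen because registry granularity varies.

The 27-feature `no_msis` schema is the default; `full` adds the MSIS-29
subscales, `basic_relapse` keeps demographics, EDSS and relapse features.
The exact feature list is declared in one place (`feature_schema()`) so it
can be revised without touching logic. Patients are split 65/5/5/25 into
train/validation/calibration/test within archetype strata, all visits
following their patient; the traditional classifiers merge train and
validation for fitting.

## Classifiers

Four model families are wrapped behind one interface: random forest
(150 trees, Gini, minimum 5 samples per leaf — the selected model), RBF-SVM
(gamma 1e-4, C=1, with internal probability calibration because conformal
scores need probability-like outputs), gradient boosting (50 rounds), and
unpenalized logistic regression. Cross-validation (`cross_validate_f1()`)
groups folds by patient: visits of one patient never straddle folds, which
prevents within-patient leakage from inflating scores. Hyperparameter search
is out of scope; the defaults are overridable per `model_spec()`.

## Numerical and design choices

* **Tie handling.** Non-smoothed p-values count ties as ≥ (conservative,
  deterministic). The smoothed variant exists only for uniformity testing.
* **Change-point statistic** (`categorize_misclassified()`): the inflection
  candidate maximizes the difference of mean SPMS p-values after vs before
  the split, scaled by $\sqrt{n_1 n_2 / n}$ so one-point tails cannot
  dominate; category 2 additionally requires two low-p visits before the
  inflection and a strictly rising robust (Theil–Sen) trend after it.
  Category 4 (fluctuating) requires at least three single-label sign
  changes; a plateau is a late-window Theil–Sen slope within ±0.01/visit.
  These thresholds codify what was a manual classification; they are
  validated on constructed series only.
* **Sustained transition**: the predicted transition is the first visit
  whose single-label SPMS prediction persists (allowing multiple-label
  visits) through the end of follow-up, with at least 2 visits in the tail —
  isolated flips are treated as unreliable, consistent with the alternation
  analysis.
* **Attribution target**: contributions are computed for the SPMS output so
  positive values push toward SPMS. Random forests get an exact tree-path
  decomposition of the vote fraction (local accuracy holds to machine
  precision by construction); gradient boosting uses exact TreeSHAP on the
  margin scale; LR/SVM use a seeded permutation estimator whose telescoping
  sums keep local accuracy exact relative to the background mean.
* **Determinism**: one RNG stream per cohort with per-patient sub-seeds, a
  seeded split shuffle, seeded model fits, single-threaded boosting. Two
  runs of `run_pipeline()` under the same configuration are byte-identical.

## Testing the conformal guarantees on clustered data

Two statistical subtleties shaped the test design, and they matter for
anyone validating conformal predictors on longitudinal data:

1. **Validity bands.** Visits cluster within patients, so the observed
   per-class error at a fixed significance has a variance two to three times
   larger than the iid binomial bound suggests, even though its expectation
   is correct. The validity check therefore averages the observed error over
   five independently simulated cohorts (≈1000 patients each) and compares
   the average against the *unchanged* single-cohort band
   $\varepsilon + 3\sqrt{\varepsilon(1-\varepsilon)/n}$ — an unbiased,
   variance-reduced estimate against the same tolerance.
2. **Uniformity testing.** Conformal p-values within one cohort share a
   calibration set and are therefore dependent; a Kolmogorov–Smirnov test
   over thousands of them is miscalibrated and rejects even for a correct
   implementation. The uniformity check instead builds exchangeable units
   (one visit per patient — patients are iid, visits within a patient are
   not), gives each replicate group its own calibration, and holds out a
   single test unit per class per group: the resulting p-values are
   independent and exactly uniform under the null, so the KS test applies.

Problem sizes used by the test suite and the acceptance script — cohorts of
1000 patients for validity (five replicates), 6000 patients for the
uniformity units, 600-patient training and 2000-patient evaluation cohorts
for transition timing — were chosen so each check has adequate power while a
full run stays within a coffee break on one core.

## Transition timing and the labelling delay

With strong class separation (`class_separation = 5`) and the labelling
delay switched off, the predicted transition visit matches the true one to
within about one visit (median) across hundreds of simulated transitioning
patients. One visit is also the resolution limit here, not a conservative
bound: the per-visit features carry disease state only through integrated
quantities (EDSS and SDMT levels, cumulative relapse counts), which still
sit at RRMS-typical values at the transition instant, so even an ideal
detector needs roughly one visit interval of post-transition accrual — the
median sits at the 1–2 visit boundary across simulation seeds however
strongly the dynamics are separated. Re-enabling
the 3-year delay, the same pipeline places the transition a median of about
one year *before* the recorded diagnosis: the classifier, trained on delayed
labels but fed features that change at the true transition, flags
progression earlier than the registry label does. That directional
discrepancy is the clinically useful behaviour the labelling-delay mechanism
exists to study, and it emerges from the simulation rather than being
asserted.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(sim = sim_config(n_patients = 300, seed = 1),
                  split_seed = 1)
run <- run_pipeline(cfg)
print(run)
plot(run$efficiency)                       # outcome fractions vs significance
plot(run$efficiency, which = "calibration")

# one transitioning patient's disease course
ta <- run$transitions
pid <- ta$patient_id[!is.na(ta$offset_visits) & ta$recorded > 1][1]
sel <- run$test$patient_ids == pid
traj <- build_trajectory(run$predictions[sel, ], run$test$visit_dates[sel],
                         as.character(run$test$y[sel]),
                         eps = run$peak_epsilon, patient_id = pid)
plot(traj)

# why did the model call this visit SPMS?
at <- local_attribution(run$model, run$test$X[which(sel)[5], ])
plot(at)
```

## Known limitations

* The simulator is an artifact: its distributions are design choices, not
  registry estimates, and none of the package's performance numbers on
  synthetic data transfer to real cohorts.
* Conformal validity is guaranteed per class *marginally*; per-visit
  validity under within-patient correlation holds only approximately (the
  expectation is right, the variance is inflated), which is exactly why the
  evaluation machinery above exists.
* The misclassification taxonomy is a codified heuristic with configurable
  thresholds; on real data its categories should be reviewed against
  clinical judgment.
* Transductive conformal prediction and sequence models over visit history
  are out of scope; the per-visit feature vector carries history only
  through carry-forward and cumulative features.
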