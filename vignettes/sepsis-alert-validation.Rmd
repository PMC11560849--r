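---
title: "Validating EHR sepsis alerts against a Sepsis-3 electronic phenotype"
author: "sepsisval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating EHR sepsis alerts against a Sepsis-3 electronic phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisval)
```

## The problem

Commercial electronic health record (EHR) systems ship proprietary sepsis
prediction models that interrupt clinicians with best-practice-advisory
(BPA) pop-ups. Whether such an alert helps depends on its diagnostic
accuracy against a reproducible sepsis definition and on *when* it fires
relative to sepsis onset: an alert that mostly follows onset tells the
clinician what they already know. `sepsisval` implements the full
external-validation workflow for such an alert in an emergency-department
(ED) cohort:

1. a Sepsis-3 electronic phenotype — total SOFA (Sequential Organ Failure
   Assessment) computed every 15 minutes, onset at the first rise of ≥ 2
   points in an encounter with blood-culture and antibiotic orders;
2. diagnostic accuracy of fired alerts under two constructions, a 6-hour
   forward window and the whole encounter;
3. a Monte-Carlo random-alert null as the chance baseline;
4. signed alert-to-onset lead-time analysis;
5. a characteristics table with chi-square tests; and
6. a synthetic-cohort generator with planted ground truth, so that every
   stage is testable end to end without patient data.

The alerting model itself is deliberately out of scope: its score is
consumed as data (an alert event with a model score and a chart-view
flag), never re-implemented.

## The SOFA engine

Six organ systems are scored 0–4 from the consensus threshold table:

| organ | driver | 1 | 2 | 3 | 4 |
|---|---|---|---|---|---|
| respiration | PaO2/FiO2 (mmHg) | < 400 | < 300 | < 200 + support | < 100 + support |
| coagulation | platelets (10³/µL) | < 150 | < 100 | < 50 | < 20 |
| liver | bilirubin (mg/dL) | 1.2–1.9 | 2.0–5.9 | 6.0–11.9 | ≥ 12 |
| cardiovascular | MAP / pressors | MAP < 70 | dopamine ≤ 5 or any dobutamine | dopamine > 5, epi ≤ 0.1, norepi ≤ 0.1 | dopamine > 15, epi > 0.1, norepi > 0.1 |
| CNS | GCS | 13–14 | 10–12 | 6–9 | < 6 |
| renal | creatinine (mg/dL) / urine | 1.2–1.9 | 2.0–3.4 | 3.5–4.9 | ≥ 5.0; urine < 500 → 3, < 200 → 4 |

Numerical conventions, all of which matter at threshold values:

* **Left-closed severity bins.** A value exactly at a printed cutpoint
  takes the milder score: platelets exactly 100 score 1, 99.9 scores 2.
* **Respiratory support cap.** Without ventilation the respiration score
  caps at 2 regardless of the ratio.
* **Renal max-of-pathways.** The renal score is the maximum of the
  creatinine-based and urine-output-based scores.
* **Cardiovascular max-over-rules.** All applicable MAP and dose rules are
  evaluated and the maximum taken.

`computeSofaSeries()` evaluates the scores on a grid that starts at ED
arrival and advances in 15-minute steps through discharge (a stay shorter
than one step yields a single-point series). At each grid time each organ
uses the most recent observation within a bounded lookback
(`carryForwardHours`, default 24 h — the "worst value per day" spirit of
SOFA applied to a rolling window). An organ with no observation in the
lookback defaults to **0 (assumed normal)** and is flagged in an
`imputed_*` column. ED patients lack many labs early in the stay; scoring
unmeasured organs as failing would label nearly everyone septic, so the
default-normal policy is the only defensible choice, and the imputation
mask keeps it auditable for sensitivity analyses. Both the lookback and
the grid step are exposed as arguments rather than fixed, since electronic
SOFA implementations differ on exactly these points.

## The phenotype

`labelCohort()` labels an encounter septic when the total SOFA rises by
≥ 2 points over the baseline *and* at least one blood culture and one
antibiotic were ordered at any time during the encounter. Onset is the
earliest grid time at which the rise first holds; by construction no
earlier grid time reaches it (first-crossing property).

Two baseline modes are provided because electronic implementations of
"an increase of 2 points" genuinely differ:

* `first_score` (default): baseline is the first computed grid score, so
  the rise is measured within the encounter;
* `zero`: baseline 0, the consensus assumption for patients without known
  pre-existing organ dysfunction. Under this mode an encounter whose first
  grid score is already ≥ 2 has onset at the first grid time.

The order requirement is encounter-level: no temporal bracketing around
onset is applied, because the phenotype is defined by the co-occurrence of
the orders with the SOFA rise during the visit, and any bracket width
would be an invention. Suspected-infection windows of the
±48 h/24 h style used elsewhere in the sepsis literature are a
deliberate non-goal.

## Alert evaluation

`extractFiredAlerts()` reduces raw alert events to at most one fired alert
per encounter: an event fires only if the model score met the alerting
threshold (default 6) **and** the chart was viewed (an interruptive BPA
can only appear to a provider looking at the chart); the earliest fired
alert anchors all downstream analysis. First-alert anchoring is the
conservative clinical reading — it is the moment the alert could first
have changed care.

Two confusion matrices are built over the same encounters:

* **Windowed** (`windowedConfusion()`): a true positive requires onset
  within `[alert, alert + 6 h]`, closed at both ends (an onset exactly at
  the horizon counts). Alerted sepsis encounters whose onset falls outside
  the window are counted as **false positives**, alongside alerted
  non-sepsis encounters. This reclassification — rather than exclusion —
  is what makes the windowed column totals interpretable: every alerted
  encounter appears in the top row, every un-alerted one in the bottom
  row, and the four cells always sum to the cohort size.
* **Whole-encounter** (`encounterConfusion()`): the window is removed; an
  alert paired with sepsis at any time (before or after the alert) is a
  true positive.

The two matrices share their FN and TN cells by construction (both depend
only on un-alerted encounters); `evaluateAlerts()` asserts this identity
on every run. `diagnosticMetrics()` reports sensitivity, specificity, PPV
and NPV as exact ratios with Wilson score intervals; a metric with a zero
denominator is `NA`, never 0.

## The random-alert null

`simulateRandomAlerts()` fires, per replicate, an independent
pseudo-alert in each encounter with probability equal to the observed
alert prevalence, at a time uniform over the stay, and pushes it through
the identical evaluation machinery. Matching the marginal alert rate is
the minimal faithful null: it answers "what would these metrics look like
if the model carried no information at this alert budget?". In
encounter mode the null specificity concentrates analytically at
1 − prevalence, which the test suite verifies to Monte-Carlo error. A
per-interval firing mode (each 15-minute interval fires independently) is
offered as an alternative mechanism, since a production model scores every
interval; its per-encounter alert probability grows with length of stay.

`adjustForRandomness()` subtracts the null sensitivity from the model
sensitivity (floored at 0). Subtraction, not a ratio, is used so that the
adjusted value remains on the sensitivity scale.

## Lead times

Among whole-encounter true positives, `computeLeadTimes()` reports
`onset − alert` in minutes (positive = alert first). The "80% interval"
is the empirical 10th–90th percentile interval of the lead-time
distribution, computed with inverse-empirical-CDF quantiles (`type = 1`)
so the closed interval provably brackets at least 80% of the lead times.
A distributional interval — not a bootstrap CI of the median — is the
interpretation consistent with intervals spanning many hours around a
median of zero at thousands of true positives. Ties (lead exactly 0)
count with "alert before or at onset", and the zero-lead count is
reported separately so any other tie convention can be reconstructed.

## The synthetic cohort generator

The generator works backwards from a planted ground truth so that every
downstream result has an exact oracle:

* `plantSkeleton()` draws sepsis status, alert status, lead times and
  grid-aligned onset times, then places discharge *after* the last planted
  event plus a log-normal tail — planted times are inside their encounter
  by construction.
* `synthesizeObservations()` gives every encounter a full normal panel at
  arrival (total SOFA 0, nothing imputed) and, at the planted onset,
  applies one of six piecewise-constant organ-failure step profiles (e.g.
  platelets dropping to 90, or MAP 62 with norepinephrine 0.05) that raise
  the total by ≥ 2 exactly there. Because everything before onset is
  normal, the phenotype's first crossing recovers the planted onset
  exactly, which is what makes count-exact round-trip tests possible.
* `synthesizeAlerts()` emits one fired alert per planted alert time plus
  decoys (sub-threshold scores with the chart viewed; above-threshold
  scores without a view) that extraction must ignore.

Default study conditions mirror the external-validation cohort the
package is designed to reproduce — a year of two county EDs with 145 885
adult encounters: sepsis prevalence 0.037, fired-alert prevalence 0.049,
alert probability 2253/5433 among sepsis encounters (the non-sepsis alert
rate is solved from the marginals), and a two-sided lead-time mixture
with weights 1126/2253 (alert after onset, uniform on (−502.5, 0)
minutes), 550/2253 (onset within the 6-hour window, uniform on [0, 360])
and 577/2253 (early alerts, uniform on (360, 951]). The negative and late
component bounds are solved so that the mixture's 10th and 90th
percentiles sit at −402 and +720 minutes, matching the reported 80%
interval; the weights reproduce both the reported 50% after-onset split
and the windowed true-positive count. (The source cohort's printed counts
of "alert ≤ 6 h before onset" and of within-window onsets are mutually
inconsistent; the defaults follow the confusion-matrix marginals and the
50/50 timing split, which also reproduce the percentile interval.)
Demographics default to that cohort's marginals. Length of stay is
log-normal (median 7 h for non-sepsis encounters, sdlog 0.9; sepsis stays
extend a log-normal tail beyond the last planted event) — a modelling
choice, as no stay distribution is published. 20% of non-sepsis
encounters receive both orders as noise, exercising the rule that orders
alone never create a label.

What the generator does **not** emulate: physiologic waveforms and
measurement noise, informative missingness, inter-organ correlation, the
alert model's score process, demographic–sepsis association (demographics
are independent of the label by default, which is exactly what the
type-I-error calibration test requires), and seasonal arrival patterns.
Passing round-trip tests therefore demonstrate the correctness of the
pipeline's logic under known structure, not the phenotype's clinical
accuracy on real EHR data.

## Worked example

```{r example, eval = FALSE}
cfg <- scenarioConfig(nEncounters = 14600, seed = 2024)
sim <- simulateCohort(cfg)
sofa <- computeSofaSeries(sim$cohort)
labels <- labelCohort(sofa, orders(sim$cohort))
ev <- evaluateAlerts(labels, alerts(sim$cohort))
ev$windowed
ev$windowedMetrics
computeLeadTimes(extractFiredAlerts(alerts(sim$cohort)), labels)
```

## Problem sizes and reproducibility

The test suite runs cohorts of 30–3 000 encounters for unit and property
tests, one 14 600-encounter cohort (one tenth of the reference cohort)
for the end-to-end reproduction, 20 000 skeletons for prevalence
calibration, and 400–500 Monte-Carlo replicates for null-model
calibration — sizes chosen so the statistical assertions (3-standard-error
bands) are sharp while the suite stays fast. All generators are
deterministic given a seed: identical configurations produce
byte-identical cohort files, and the null model restores the caller's RNG
state.

## Known limitations

* The default-normal imputation understates severity for organs that are
  simply unmeasured; the imputation mask is the supported route to
  sensitivity analyses.
* The characteristics table reports Pearson chi-square (and optionally
  likelihood-ratio) p-values computed from the counts. For the reference
  cohort's race distribution these counts are decisively non-uniform
  (chi-square p ≪ 0.001), whereas the source analysis reported a
  non-significant regression-based p-value for race from an unpublished
  model; that regression cannot be reproduced from counts alone and is
  not attempted.
* Whether the 6-hour evaluation window should be one-sided is a genuine
  ambiguity in this analysis style; the one-sided forward window is the
  default here, and the whole-encounter analysis covers the two-sided
  reading.
* Lead-time statistics are conditional on being a true positive; they say
  nothing about the 58.5% of sepsis encounters that were never alerted.
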