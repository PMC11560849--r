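# sepsisval

External validation of EHR sepsis alerts against a Sepsis-3 electronic
phenotype.

Hospital EHR systems interrupt clinicians with proprietary sepsis-model
pop-up alerts. This package implements the complete workflow for judging
such an alert in an emergency-department cohort: it computes Sequential
Organ Failure Assessment (SOFA) scores every 15 minutes from raw
observations, labels sepsis onset with the Sepsis-3 electronic phenotype,
evaluates fired alerts with windowed and whole-encounter confusion
matrices, benchmarks them against a Monte-Carlo random-alert null, and
summarises alert-to-onset lead times. A synthetic-cohort generator with
planted ground truth makes the whole pipeline testable without any
patient data.

## The phenotype and the evaluation

Sepsis onset is the first grid time `t` (15-minute grid from ED arrival)
at which

```
SOFA_total(t) − SOFA_baseline ≥ 2
```

in an encounter where at least one blood culture **and** one antibiotic
were ordered (the baseline is the first computed grid score by default,
or 0). The six organ sub-scores (respiration, coagulation, liver,
cardiovascular, CNS, renal; each 0–4) use the consensus cutpoint table
with left-closed severity bins, bounded last-observation-carried-forward
imputation (24 h), and default-normal scoring of unmeasured organs.

A *fired* alert requires model score ≥ 6 **and** a chart view; the first
fired alert per encounter anchors the evaluation. In the windowed
analysis a true positive requires onset within `[alert, alert + 6 h]`;
alerted encounters with out-of-window onset count as false positives, so
the four cells always sum to the cohort size. Metrics are

```
sensitivity = TP/(TP+FN)   specificity = TN/(TN+FP)
PPV = TP/(TP+FP)           NPV = TN/(TN+FN)
```

each with Wilson 95% intervals. The random-alert null fires a
pseudo-alert per encounter with probability equal to the observed alert
prevalence at a uniform time; `adjustForRandomness()` subtracts the null
sensitivity from the model's. Lead time is `onset − alert` in minutes
(positive = alert first), summarised by the median and the empirical
10th–90th percentile interval.

## Worked example

```r
library(sepsisval)

cfg <- scenarioConfig(nEncounters = 2000, seed = 42)   # defaults: 3.7% sepsis, 4.9% alerts
sim <- simulateCohort(cfg)
sofa <- computeSofaSeries(sim$cohort)                  # 15-min grid, 24-h LOCF
labels <- labelCohort(sofa, orders(sim$cohort), quiet = FALSE)
#> labelled 2000 encounters: 93 sepsis (4.7%)

ev <- evaluateAlerts(labels, alerts(sim$cohort))       # 6-h window + encounter
ev$windowed
#> ConfusionMatrix (windowed, 6 h window)
#>        sepsis no sepsis
#> alert+     10        88
#> alert-     59      1843
ev$windowedMetrics
#>        metric  estimate      lower     upper
#> 1 sensitivity 0.1449275 0.08067095 0.2466352
#> 2 specificity 0.9544278 0.94418902 0.9628620
#> 3         ppv 0.1020408 0.05637600 0.1777277
#> 4         npv 0.9689800 0.96019390 0.9758756

computeLeadTimes(extractFiredAlerts(alerts(sim$cohort)), labels)
#> Lead-time summary over 34 true-positive encounters
#>   median lead: 46 min (80% interval -391 to 662 min)
#>   alert before/at onset: 55.9%   after onset: 44.1%
```

The windowed matrix says: of 98 alerted encounters only 10 developed
sepsis within six hours of the alert (PPV 10%), and 59 of 69 sepsis
encounters were never alerted (sensitivity 14%) — at this scale the
alert's information content is close to its false-positive budget, which
is exactly what the lead-time split (44% of alerts after onset) also
shows. At reference scale (145 885 encounters) the same machinery on the
published counts gives sensitivity 14.7%, specificity 95.3%, PPV 7.7%,
NPV 97.7%:

```r
diagnosticMetrics(ConfusionMatrix(tp = 550, fp = 6633, fn = 3180, tn = 135522))
#>        metric   estimate      lower      upper
#> 1 sensitivity 0.14745308 0.13643750 0.15919408
#> 2 specificity 0.95333966 0.95223097 0.95442386
#> 3         ppv 0.07656968 0.07064419 0.08294783
#> 4         npv 0.97707315 0.97627217 0.97784770
```

A thin CLI mirrors the pipeline stages
(`exec/sepsisval simulate|sofa|label|evaluate|null|timing|report`); the
cohort file schemas are documented in `?readCohort`.

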