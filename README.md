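# microstatr

Resting-state EEG microstate analysis for case-control studies, with a
built-in synthetic-EEG generator that makes every stage of the pipeline
verifiable against a planted ground truth.

## What problem this addresses

Spontaneous EEG alternates between a handful of quasi-stable scalp
topographies ("microstates", canonical classes A-D) on a 60-120 ms
timescale. Clinical studies compare their temporal parameters — per-class
mean duration, occurrence rate, time coverage and between-class transition
probabilities — between patient and control groups, and correlate them
with symptom scales. The analysis chain behind such studies (GFP-peak
extraction, topographic clustering, backfitting, temporal smoothing,
covariate-adjusted group statistics) involves many interacting choices, and
none of the intermediate stages can be checked against public data when the
recordings are not released. `microstatr` implements the full chain *and*
its generative inverse: a semi-Markov simulator that plants known
dynamics, so recovery of durations, occurrences, coverages, transitions and
planted clinical correlations can be demonstrated end to end.

## The method in brief

* **GFP** at time *t* is the population SD of the average-referenced map
  `u(t)` across electrodes; maps at strict within-epoch GFP peaks carry
  the best-defined topographies.
* **T-AAHC** clusters those maps under polarity-invariant spatial
  correlation `|r(u, v)|`: starting from singletons, the cluster with the
  smallest contribution to `GEV = Σ (GFP_i · r_i)² / Σ GFP_i²` is
  repeatedly dissolved and its maps reassigned by highest `|r|`;
  centroids are first principal axes of member maps.
* **Backfitting** labels each frame with `argmax_k |r(u(t), T_k)|`;
  segments of ≤ 20 frames are dissolved into their flanks, and per class
  the mean duration (ms), occurrence (1/s), coverage (%) and
  row-conditional transition matrix are extracted (coverage =
  occurrence × duration holds by construction).
* **Group statistics**: ANCOVA per parameter, `y ~ education + group`,
  `F(1, n-3)` with partial `η² = SS_group/(SS_group+SS_resid)`,
  Benjamini-Hochberg FDR per parameter family; pooled-variance t and
  Yates-corrected χ² for demographics; Pearson r with Fisher-z 95% CIs
  (`tanh(atanh(r) ± 1.96/√(n-3))`) for symptom correlations.

## Worked example

```r
library(microstatr)

dyn_pat <- dynamics_spec(c(A = 60, B = 55, C = 68, D = 62), snr = 10)
dyn_ctl <- dynamics_spec(c(A = 60, B = 65, C = 58, D = 62), snr = 10)
spec <- cohort_spec(n_per_arm = c(patient = 3, control = 3),
                    dynamics = list(patient = dyn_pat, control = dyn_ctl),
                    length_s = 20, fs = 1000)
cohort <- simulate_cohort(spec, seed = 42)
analysis <- run_microstate_pipeline(cohort$recordings, cohort$subjects)
analysis
#> <ms_analysis> 6 subjects, mean subject GEV 0.965
head(analysis$params[, c("subject", "arm", "class", "mean_duration_ms",
                         "occurrence_per_s", "coverage_pct")], 4)
#>   subject     arm class mean_duration_ms occurrence_per_s coverage_pct
#> 1  sub-01 patient     A            62.00             3.30        20.46
#> 2  sub-01 patient     B            64.39             3.50        22.54
#> 3  sub-01 patient     C            79.52             3.85        30.61
#> 4  sub-01 patient     D            66.81             3.95        26.39
```

The mean subject GEV of 0.965 says the four templates explain ~96% of the
GFP-weighted topographic variance at the peaks. Each row gives one
subject's per-class parameters: e.g. subject 1 spends 30.6% of analyzed
time in class C, entering it 3.85 times per second with an average dwell
of 79.5 ms. Comparing against the planted truth:

```r
err <- recovery_errors(cohort, analysis)
err$parameters[err$parameters$measure == "duration", ]
#>   class  measure recovered planted rel_error
#> 1     A duration      67.3    60.3    0.1161
#> 2     B duration      65.7    58.3    0.1260
#> 3     C duration      72.3    66.9    0.0808
#> 4     D duration      69.6    63.8    0.0921
```

Twenty-second recordings are deliberately short for a quick example; at
the validated scale (60-s recordings, SNR 10, 10 subjects) the
cohort-mean errors of all four parameter families fall below 10%. Group
statistics on the extracted tables come from
`run_group_analysis(analysis$params, analysis$transitions,
cohort$clinical)`, and `write_analysis_report()` exports them as
TSV + JSON.

Statistics computable directly from published summary numbers need no
simulation, e.g.

```r
summary_ttest(26.40, 7.36, 30, 24.10, 5.99, 40)$t   # 1.4409
pearson_ci_summary(-0.403, 30)$ci                   # -0.6665 -0.0500
```

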