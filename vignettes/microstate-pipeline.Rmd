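---
title: "Microstate dynamics from resting-state EEG: model, pipeline and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate dynamics from resting-state EEG: model, pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Resting-state EEG spends most of its time in a small number of quasi-stable
scalp topographies — microstates — each lasting on the order of 60–120 ms
before switching abruptly to another. Four canonical map classes recur
across studies: a right-frontal to left-posterior axis (A), its left-right
mirror (B), an anterior–posterior midline pattern (C) and a fronto-central
maximum (D). `microstatr` implements the standard analysis chain that turns
a multichannel recording into per-class temporal parameters, and a
generative counterpart of that chain so that every stage can be validated
against a known ground truth.

The analysis proceeds in the conventional order:

1. **Preprocessing** (`preprocess_recording()`): zero-phase Butterworth
   band-pass (1–40 Hz broad band, then 2–20 Hz for microstate analysis,
   both applied to the continuous record before epoching), segmentation
   into consecutive 2-s epochs, rejection of any epoch containing a sample
   with |v| > 100 µV (strict inequality; a sample exactly at the threshold
   is kept), then common average referencing. Amplitude screening is
   applied before re-referencing, matching the usual ordering of the
   conditioning chain.
2. **GFP-peak clustering** (`gfp()`, `gfp_peaks()`, `taahc()`): global
   field power is the population standard deviation across electrodes of
   the average-referenced map at one instant; maps at strict within-epoch
   GFP maxima are clustered by topographic atomize-and-agglomerate
   hierarchical clustering under polarity-invariant spatial correlation
   (|Pearson r| across channels).
3. **Group templates and labeling** (`group_templates()`,
   `assign_canonical_labels()`): subject-level templates are pooled and
   re-clustered; the four group maps are put into canonical A–D order by
   the one-to-one matching that maximizes summed |r| against a reference
   set (exhaustive over the 4! pairings).
4. **Backfitting and smoothing** (`backfit()`,
   `reject_short_segments()`): every frame takes the label of the
   best-correlating template; segments of ≤ 20 frames (20 ms at 1000 Hz)
   are iteratively dissolved, each frame joining the flanking segment
   whose template correlates better with it.
5. **Parameters** (`temporal_parameters()`, `transition_matrix()`): per
   class, the mean segment duration (ms), occurrence (appearances per
   second of analyzed time) and coverage (percent of labeled frames), plus
   row-conditional transition probabilities counted at within-epoch
   segment boundaries. These satisfy the run-length identity
   coverage = occurrence × mean duration.
6. **Group statistics** (`run_group_analysis()`): ANCOVA of each parameter
   on group with education as covariate (F on 1 and n−3 df, partial
   η² = SS_group/(SS_group+SS_resid)), Benjamini–Hochberg FDR within each
   parameter family, pooled-variance t and Yates-corrected χ² for
   demographics, and Pearson correlations with Fisher-z 95% CIs between
   clinical scores and FDR-surviving parameters in the patient arm.

## The generative model

`simulate_cohort()` produces artifact-free cohorts with exported ground
truth. Its ingredients, and the reasoning behind each default:

* **State sequence** — a semi-Markov chain: dwell times are drawn per
  class from a gamma distribution with the class's mean duration and shape
  4, truncated below at 10 ms and rounded to whole frames; the successor
  class is drawn from a conditional transition matrix with zero diagonal
  (uniform over the other classes by default). Shape 4 gives a
  right-skewed dwell distribution whose bulk sits in the observed
  60–120 ms quasi-stability band; a geometric law (plain Markov chain)
  would put far too much mass on very short dwells.
* **Signal** — each frame is the unit-norm template of its class scaled by
  a 10 Hz sinusoidal carrier (the dominant eyes-closed alpha rhythm),
  a per-segment amplitude drawn uniformly in 0.7–1.3, and a 40 µV scale.
  A sinusoidal carrier yields GFP peaks twice per cycle, the structure the
  peak-extraction step relies on. Carrier polarity reversals within a
  segment are intentional: the entire analysis chain is polarity-blind.
* **Noise** — spatially white Gaussian noise, scaled so that the ratio of
  state-signal RMS to noise RMS equals the requested SNR. This is the
  simplest model that exercises the recovery question; it deliberately
  omits 1/f background, volume-conducted artifacts, and ocular/muscle
  components (no ICA stage exists downstream, so none is needed).
* **Templates** — each canonical class is synthesized as two
  opposite-signed Gaussian sources on a schematic 64-channel 10–20 layout,
  average-referenced and unit-normed. Source positions encode the
  canonical orientations; all pairwise |r| between the four maps are below
  0.7. A `jitter` parameter adds per-channel topographic variability
  across subjects (default 0, since between-subject map variability is
  not quantified in the literature this package targets).
* **Cohorts** — per-subject mean durations jitter log-normally around the
  arm means (CV 0.08, a modest between-subject spread); clinical scores
  are built by a bivariate-normal construction so a named score (default:
  the HAMD-24 anxiety/somatization factor, target moments 5.50 ± 2.61)
  attains a planted correlation with a named subject-level dynamics
  parameter, then is rounded and clipped to the instrument range and
  distributed over the factor's items. Demographics are drawn from
  per-arm normal/binomial models matching a 30-patient/40-control study
  (education 14.30 ± 3.53 vs 15.85 ± 2.55 years, etc.).

What passing recovery tests do and do not show: they demonstrate that the
analysis chain is a consistent estimator of the planted dynamics under
alpha-band carriers and white noise at SNR ≥ 10. They do not certify
performance on real recordings, where line noise, non-stationary artifacts,
imperfect electrode placement and genuine topographic variability all
degrade clustering — those factors are out of the generator's scope by
design.

## Numerical choices

* **Filtering** is a forward–backward (zero-phase) Butterworth cascade,
  4th-order high-pass then 4th-order low-pass per band. The cascade form
  is numerically safer than a single narrow-band recursion at 1 Hz/1000 Hz
  relative edges; the 10 Hz passband gain is within 0.1% of unity and
  50 Hz is attenuated by far more than 20 dB.
* **T-AAHC details**: the cluster dissolved at each step is the one
  contributing least to GEV = Σ(GFP·|r|)²/ΣGFP²; orphan maps join the
  cluster of highest |r| with ties going to the lowest cluster index;
  centroids are the first principal axis of the member maps (the leading
  eigenvector of the summed outer products), which is polarity-blind,
  with the sign chosen to agree with the majority of members. Plain
  averaging would cancel under polarity flips, so it is not used.
* **Short-segment rejection** dissolves the shortest qualifying segment
  first (earliest on ties) and re-derives segments after every
  dissolution, iterating to a fixed point at which no interior segment of
  ≤ 20 frames remains. Epoch-edge segments are exempt — they are
  truncated, not genuinely short. A sequence with no labeled frames
  beyond the threshold is returned unchanged with a warning.
* **Degenerate inputs**: zero-variance frames are unlabelable and inherit
  the nearest labeled neighbor within the epoch; zero-variance maps make
  spatial correlation undefined (`NA` with a warning); an all-zero
  transition row, a constant covariate, or a zero score SD with a nonzero
  planted correlation are rejected with explicit errors.
* **Transition matrices** are row-conditional (probabilities out of each
  source class sum to 1), matching the row→column reading of transition
  heat maps; the jointly normalized matrix is also returned, since
  "across all observed transitions" admits either normalization.

## Open design points and how they were resolved

* **Pooled vs per-arm templates.** Whether group templates should come
  from all participants pooled or from each arm separately is genuinely
  ambiguous in practice. Pooling is the default here because backfitting
  the same maps to everyone is what makes temporal parameters comparable
  across arms; `template_scope = "per_arm"` provides the alternative.
* **Amplitude rule boundary.** "Exceeding ±100 µV" is implemented as a
  strict inequality, so a sample at exactly 100 µV survives.
* **Smoothing reassignment.** Dissolved frames are reassigned by
  frame-wise template correlation with the two flanking segments rather
  than split midway; when no correlation matrix is available (labels
  imported from elsewhere), the midpoint split is the fallback.
* **Occurrence denominator** is analyzed (kept-epoch) time, not nominal
  recording length: rejected epochs carry no labels.
* **HAMD-24 factor map.** The seven-factor structure with
  anxiety/somatization = {psychic anxiety, somatic anxiety,
  gastrointestinal, general somatic, hypochondriasis, insight} is the
  conventional one; it is supplied as a default and is overridable, since
  published studies do not always print their exact item mapping.

## Validation scale

The test suite validates every operation against closed forms or
independent brute-force oracles, and the two simulation-heavy checks run
at sizes chosen to keep the full suite in the minutes range while leaving
Monte-Carlo error well inside the asserted tolerances: ground-truth
recovery uses 10 subjects × 60 s at 1000 Hz and SNR 10 (cohort-mean
parameter errors are asserted below 10% relative), and the type-I
calibration of the group ANCOVA uses 200 replicate null cohorts of
30 + 40 subjects simulated at the label-sequence level. Sequence-level
simulation is used for calibration deliberately: the EEG synthesis and
clustering stages are identical across arms under the null, while the
extraction-plus-inference chain is the part whose error rate needs
calibrating. `scripts/acceptance.R` re-runs both studies from scratch at
the same sizes.

## Limitations

* The generator's noise model is white and Gaussian; real EEG noise is
  colored and spatially correlated.
* The schematic montage preserves left/right and anterior/posterior
  structure but not true electrode geodesics; it is sufficient for
  orientation checks and template synthesis, not for source modeling.
* No ICA-based artifact removal: only the quantitative amplitude rule is
  implemented, so heavily contaminated real data should be cleaned before
  entering this pipeline.
* `k` is fixed at 4 by default and no model-selection criterion for the
  number of classes is provided.
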