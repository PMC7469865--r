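---
title: "Trial-averaged ERP decoding of spatial attention: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-averaged ERP decoding of spatial attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdecode)
```

## The analysis model

`erpdecode` implements a complete analysis chain for cued visual spatial
attention EEG: signal conditioning, artifact screening, univariate ERP
measurement, trial-averaged multivariate decoding, group-level inference on
the decoding time course, and between-subject brain-behavior linkage. The
scientific premise is that the attentional state (which hemifield is
attended; whether a target was attended) is encoded in the *pattern* of
voltage across the scalp rather than in any single electrode, and that a
linear classifier applied to trial-averaged patterns can track that state
with ~20 ms resolution.

Key assumptions, stated explicitly:

* **Trial averaging before classification.** Attention-related slow
  components are small (< 1 uV) against single-trial noise; averaging
  trials within random groups trades trial count for signal-to-noise. The
  procedure assumes trials within a condition are exchangeable.
* **Linear decodability.** A linear SVM (cost 1) on z-scored channel
  patterns; the z-scoring (mean 0, sample SD 1 across channels within each
  group-averaged pattern) removes common offsets such as slow drifts, so the
  classifier sees only the *shape* of the topography.
* **Phase-locked features.** The 8 Hz two-way least-squares FIR low-pass
  (order `3 * floor(sfreq/cutoff)` = 93 at 250 Hz) is applied before
  averaging so decoding reflects ERP activity, not alpha-band oscillations;
  an alpha-power feature path (`alpha_power_features()`) exists as the
  explicit control analysis.
* **Two-class structure with 50% chance.** Accuracy per time point is the
  fraction of correct predictions over 2 conditions x 3 folds x 20
  iterations = 120 attempts (the defaults of `decoder_config()`).

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_groups` | 3 | groups | leave-one-group-out CV; remainder trials omitted per partition |
| `n_iterations` | 20 | re-partitions | stabilizes the accuracy against the random trial split |
| `cost` | 1 | -- | SVM regularization; the conventional default of the libsvm family (not specified by the procedure itself) |
| `smoothing_points` | 5 | points | +/-40 ms moving average at 50 Hz |
| low-pass cutoff | 8 | Hz | keeps ERP content, suppresses alpha |
| trim | 200 | ms | discards filter edge artifacts; epochs are extracted longer than analyzed |
| FDR level | 0.05 | q | Benjamini-Hochberg across time points |
| contiguity | 3 | points | removes isolated significant points |
| bootstrap | 100 | resamples | onset uncertainty across subjects |
| permutations | 1000 | iterations | cluster-size null distribution |
| N1 window / ROIs | 170-210 ms; 3 or 7 posterior channels per hemisphere | ms | conventional mean-amplitude measurement, contralateral to the target |

Artifact screening applies four criteria whose union rejects a trial:
moving-window peak-to-peak (200 ms / 50 ms / 150 uV), absolute voltage
(100 uV), an HEOG step function (400 ms / 10 ms / 40 uV), and a VEOG blink
detector (200 ms / 10 ms / 50 uV) restricted to -200..200 ms around
stimulus onset. Millisecond windows are converted to samples with
`max(1, round())`; only windows fully inside the epoch are evaluated
(partial end windows are skipped, matching full-window semantics of the
standard screening tools).

## The synthetic cohort generator

Because real recordings of this kind are not publicly deposited, the
package ships a generator (`sim_config()`, `generate_cohort()`) that
emulates the statistical structure the analysis assumes, with full ground
truth for recovery testing:

* **Cue epochs** carry a lateralized slow component (posterior pair with a
  weaker opposite-polarity frontal pair, unit-norm Gaussian bumps on a
  schematic 10-20 montage, sign mirrored for cue-left vs cue-right) that
  ramps up over 200 ms from a subject-specific onset. Population onsets of
  80 ms ("instructional-like") and 160 ms ("probabilistic-like") encode the
  two cueing strategies.
* **A late posterior bump** (Gaussian in time over the 460-660 ms window)
  carries the planted individual-differences coupling: its subject
  amplitude is the subject's effect amplitude times an independent
  log-normal factor, and the planted N1 modulation is linear in it.
* **Target epochs** contain a contralateral N1 (Gaussian kernel peaking at
  185 ms, sd 25 ms) whose cued-uncued difference is the planted modulation
  (negative sign maintained), plus a later fronto-central difference
  component scaled with the modulation so target decodability extends
  beyond the N1 and couples to reaction times.
* **Background noise** is 1/f (exponent 1, 6 uV per channel by default)
  spatially mixed by a per-subject random orthonormal matrix -- giving the
  non-diagonal channel covariance the activation-pattern (covariance times
  weights) transform needs -- plus posterior-weighted 8-13 Hz narrowband
  noise (10 uV^2). Subject effect amplitudes are log-normal: positive,
  right-skewed heterogeneity for the between-subject correlations.
* **Reaction times** are Gaussian per trial around
  `baseline - rt_coupling * |N1 modulation|`, with a validity cost added to
  uncued-target trials in the probabilistic design; mean and median
  summaries are both emitted.
* All randomness derives from one master seed through deterministic
  substreams (`derive_seed()`), so cohorts are bit-identical under a fixed
  configuration.

The default effect amplitude (1 uV) is a *calibration*, not ground truth:
it was chosen once so that a default cohort's group decoding time course
sits in the qualitatively realistic regime (chance before the cue, a rise
after the planted onset, a plateau around 0.75 at 240 trials per
condition). What the generator does **not** emulate: biophysical forward
models and realistic ocular dipole geometry, non-stationary noise, drifting
electrode impedances, or ICA-correction residue. Passing recovery tests on
these cohorts therefore validates the *statistical machinery*, not the
physiological faithfulness of any given real dataset.

## Numerical choices and degenerate inputs

* Epoch windows are half-open `[start, end)` on the sample grid, so the
  canonical cue window (-800..1200 ms at 50 Hz) has exactly 100 points and
  the target window (-300..800 ms) exactly 55; the inclusive convention
  would give 101/56. The N1 window (170-210 ms) is endpoint-inclusive,
  matching mean-amplitude conventions.
* Downsampling is decimation (every k-th sample) after the 8 Hz low-pass,
  which doubles as the anti-alias filter; the alpha-power path gets an
  explicit 20 Hz anti-alias low-pass because envelope content exceeds 8 Hz.
* The least-squares FIR design leaves a small passband ripple (the 93rd
  order 8 Hz filter passes DC at gain ~1.02 per pass); tests assert against
  the filter's own frequency response rather than an idealized identity.
* Zero-variance patterns z-score to all-zeros rather than NaN; degenerate
  SVM training sets (identical patterns, opposite labels) fall back to a
  deterministic first-label rule, making toy inputs decode at exactly 0.5.
* Signed-rank tests use the exact distribution for n <= 25 informative
  (non-zero, untied) differences and the continuity-corrected normal
  approximation otherwise; zero differences are dropped; an all-zero time
  point yields p = 1 with a warning.
* Liptak-Stouffer combination clips p values to `[1e-12, 1 - 1e-12]`
  before the probit transform.
* Onset search is restricted to t >= 0: pre-stimulus significant points
  (possible under noise) are never reported as onsets. Bootstrap resamples
  with no onset are excluded from the summary and counted.
* Cluster p values use the `>= observed` percentile convention (ties count
  as exceeding, conservative); an observed size beyond every null value is
  flagged as `p < 1/n_perm`. Permutations are uniform shuffles (identity
  allowed). Because cluster sizes are small integers the attainable test
  levels are discrete; how close the attained family-wise error comes to
  the nominal 0.05 depends on the null series' temporal structure. On pure
  smoothed noise it is conservative (~0.02); on series with the
  subject-level offsets the pipeline's null decoding actually exhibits
  (per-subject mean accuracy spread ~0.08 at these trial counts, from slow
  1/f drift and partition luck) it sits at ~0.05.

## Design choices where the design was open

* The cue-side spatial templates are fixed unit-norm Gaussian topographies,
  not a forward model: they reproduce frontal-posterior lateralized weight
  maps qualitatively at a fraction of the cost.
* Per-class z-normalization (within each group-averaged pattern) is the
  default; normalization across classes jointly is not offered because the
  within-class form is the one that removes class-common drifts.
* The activation-map covariance is computed from the normalized training
  patterns per time point (per fold, averaged over folds and iterations);
  raw-feature or pooled covariance would be alternatives, but the
  per-timepoint normalized form matches what the classifier actually saw.
* N1 side-averaging weights the two target sides equally rather than by
  trial count (an assumption; counts are near-equal by design anyway).
* For bootstrap onset distributions the whole inference chain (signed-rank,
  FDR, contiguity, onset) is recomputed inside each resample -- the
  statistically coherent reading, rather than reusing the original mask.
* The 50 Hz notch is an equiripple FIR band-stop with a 49-51 Hz stopband
  and 3 Hz transitions (order 200); the published chain names only the
  design family and frequency, so the bandwidth and ripple are exposed as
  configuration.
* The HEOG microvolt-to-degree conversion (16 uV/deg) is a literature
  convention, exposed as an argument.
* No shell entry point is shipped: the exported functions
  (`run_cue_pipeline()`, `run_target_pipeline()`, `run_linkage()`) are the
  orchestration interface, and all artifacts are written as CSV/JSON with a
  manifest (config echo, seeds, md5 checksums).
* With no HDF5 library available to R in this toolchain, the epoch
  container serializes to a plain-text directory layout (`write_epochset()`:
  JSON metadata + CSV matrices) that round-trips exactly.

## Problem sizes used in the validation suite

The test suite validates the chain at desk scale, chosen so the full suite
runs in well under half an hour on one CPU:

* *Chance calibration*: 20 single-subject null cohorts (60 trials per
  condition, 30 channels) through the full pipeline; the grand-mean smoothed
  accuracy must lie within the Monte-Carlo 95% CI of 0.5.
* *Family-wise error*: 500 null replicates (26 subjects, 60 time points;
  subject-level offsets of sd 0.08 plus 5-point-smoothed noise, matching
  the null pipeline's measured structure; 1000 permutations each); the
  fraction with any significant cluster must fall in 0.05 +/- 0.02.
* *Onset recovery*: two 12-subject cohorts at high planted SNR (8 uV
  effect), onsets 80 vs 160 ms; bootstrap means must recover the plants
  within one 20 ms step and the t comparison must be negative (earlier
  instructional-like onset).
* *Coupling recovery*: twenty replicates of a two-cohort (20 + 20 subjects,
  125 Hz, shortened epochs) design with the N1-coupled late bump; the
  meta-analytic cluster permutation must find a significant negative-r
  cluster overlapping 460-660 ms in at least 16 of 20 replicates. The
  125 Hz rate and 36 trials per condition keep each replicate under a
  minute; the per-point Pearson correlation is the power-limiting factor
  (frozen trial noise per subject caps it near -0.6 at realistic noise), so
  this test leans on the two-dataset Liptak-Stouffer combination exactly as
  the full analysis does.
* *Ocular confound*: an 8-subject null cohort with a 15 uV condition-locked
  frontal artifact injected; F7/F8-only decoding must exceed chance late in
  the cue-target interval with the artifact present and return to chance
  when it is absent or its sign is randomized.

## Known limitations

* The generator's spatial templates are schematic; activation-map tests
  assert correlation with the planted template, not anatomical validity.
* Linear-phase FIR smearing (two-pass kernel support of several hundred ms
  at order 93) biases high-SNR onset estimates early by up to one or two
  20 ms steps; onset recovery is therefore specified within +/-20 ms.
* Only two-class decoding is implemented (no multi-class, no temporal
  generalization, no single-trial decoding).
* The cluster permutation's discreteness makes it conservative for short
  time series; with very few time points the attainable family-wise error
  can fall well below the nominal level.
* Continuous-recording import (vendor formats) is out of scope; analyses
  start from epoched arrays or the package's own container.
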