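---
title: "Methods: simulating and classifying affect from peripheral physiology"
author: "emophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying affect from peripheral physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emophys)
```

## The analysis

`emophys` implements a complete affect-recognition analysis for
multimodal peripheral physiology recorded under a block-design picture
induction of five core affects — neutral and the four quadrants of the
valence–arousal plane (HVHA, HVLA, LVHA, LVLA). The stages are:

1. **Signal conditioning.** Facial EMG over the corrugator supercilii
   and zygomaticus major is band-passed at 20–250 Hz (4th-order
   Butterworth, forward–backward so the phase is zero and events stay
   aligned with the stimulus timeline), a narrow IIR notch (Q = 30)
   suppresses 50 Hz line interference, and the envelope is the 125 ms
   sliding-window RMS. Skin conductance is smoothed with a 0.2 Hz
   4th-order Butterworth low-pass (zero phase, unit DC gain). Inter-beat
   (NN) intervals are extracted from the blood-volume pulse by peak
   detection on the 0.5–8 Hz band-passed signal with a 300 ms minimum
   inter-peak distance.
2. **Features.** Per stimulation block: five time-domain HRV features
   (mean/SD of NN, mean/SD of heart rate, RMSSD with the 1/(n−1)
   normalization under the root); baseline-corrected mean EMG envelope
   per site (mean over the block minus the mean over the 2 s before
   block onset), z-scored within subject and site across blocks; and
   thirteen SCL features (mean, SD, lag-1 and lag-2 mean absolute
   differences of the raw and within-segment z-scored signal, counts and
   mean amplitudes of extrema exceeding 0.05 µS, the integral over time,
   and the least-squares slope). The two blocks of each condition are
   averaged, giving one row per subject × condition with 20 features.
3. **Redundancy reduction.** Pairwise Pearson correlations over all
   rows; while any pair reaches |r| ≥ 0.95 the higher-indexed member of
   the most-correlated pair is dropped and correlations are recomputed.
   Greedy highest-|r|-first removal with canonical-order tie-breaks
   makes the procedure deterministic.
4. **Screening.** Age, the two BSRI gender-role scores, NEO-FFI
   extraversion and neuroticism, BIS and BAS are Pearson-correlated with
   every feature in every condition; two-sided p-values use the t
   transform with n − 2 degrees of freedom, and significance applies the
   Bonferroni-corrected level 0.05/7 ≈ 0.007. Gender is deliberately
   excluded here; it enters through subgrouping.
5. **Classification.** An RBF-kernel SVM with inverse-class-frequency
   weights is validated leave-one-subject-out (LOSO): all rows of the
   held-out subject are predicted by a model that never saw that
   subject, with feature scaling fit on the training rows only. Wrapper
   feature selection (greedy forward selection or backward elimination,
   scored by an inner LOSO over the training subjects only) runs per
   outer fold; when both wrappers run, the reported accuracy is their
   maximum. Tasks: the 3-class valence split (neutral / positive =
   HVHA + HVLA / negative = LVHA + LVLA), the 5-class problem, and
   neutral against each arousing condition. Analyses repeat per
   gender × age subgroup (cutoff 45 years between "young" and
   "elderly").

## The synthetic cohort

Real recordings of this kind cannot ship with a package, so the
`synthetic_data` stage is a first-class, tested component that generates
cohorts with the statistical structure the analysis assumes. Defaults
reproduce the reference paradigm: 100 subjects, 64% female, ages
uniform on 20–75, five conditions × two blocks, ten 2 s pictures per
block, 20 s fixation before every block — a 400 s session. (Published
descriptions of this paradigm are ambiguous between 10 and 20 pictures
per block; with 5 conditions × 2 blocks and 100 pictures in total, 10
per block is the only consistent reading, and the count is
configurable.)

Injected structure, all configurable through `effect_params()`:

* **Age effect.** Tonic SCL = 8 µS at the age midpoint, −0.05 µS/year,
  against a 1.6 µS between-subject SD — targeting a population age–SCL
  correlation near −0.45 in a 100-subject cohort.
* **Condition effects.** Corrugator envelope reactivity is highest
  under negative valence, zygomaticus under positive valence; skin
  conductance responses (one difference-of-exponentials event per
  picture onset, rise 0.75 s, decay 2 s) are largest under high
  arousal; heart periods shorten by 5–30 ms under arousal.
* **Gender × condition modulation.** Phasic reactivity (SCR amplitudes
  and EMG reactivity above rest) is multiplied by 2 for females under
  LVHA and for males under HVHA.
* **Realistic messiness.** Reactivity varies log-normally between
  subjects (SD 0.4) and between blocks (SD 0.8), block tone fluctuates
  additively, 30% of pictures elicit only a minimal (10%) electrodermal
  response, per-picture SCR amplitudes jitter log-normally (SD 0.5),
  inter-beat intervals carry 30 ms Gaussian jitter, SCL drifts slowly
  and carries measurement noise, and each EMG channel includes a 50 Hz
  interference sinusoid.

The magnitudes were fixed once, by two calibration requirements stated
up front: (i) accuracies on default cohorts should fall where published
studies of this paradigm land them — five-class LOSO accuracy far above
the 20% chance level yet well below ceiling, binary tasks in the
85–95% range — rather than the ~100% a low-noise generator yields; and
(ii) the injected age and gender effects must be recoverable by the
package's own screening and subgroup stages at the cohort sizes used in
the tests. The gender gain of 2 is the value at which the female-LVHA
and male-HVHA subgroup advantages survive the smaller training sets of
subgroup classification.

What the generator does **not** emulate: realistic cardiac waveform
morphology, respiration and motion artifacts, SCR habituation trends,
EMG bursts with realistic spectra (block envelopes modulate white
noise), or questionnaire item-level structure (trait scores are drawn
directly as truncated normals within instrument ranges: NEO-FFI 0–48,
BIS 7–28, BAS 13–52, BSRI 1–7). Green tests therefore certify the
pipeline's correctness and its statistical behaviour under the injected
effects — not performance on real recordings.

## Numerical choices

* **Filtering.** All filters are applied forward–backward with
  odd-reflection padding, using Butterworth coefficients from
  `signal::butter` and an exact C-backed recursion; the SCL low-pass
  anchors the signal at its first sample before filtering because an
  order-4 low-pass at 0.2/16 normalized frequency is poorly conditioned
  around large tonic offsets.
* **"Adaptive" line removal** is a fixed second-order notch (Q = 30)
  applied zero-phase: an equivalent contract (≥ 20 dB at 50 Hz, < 3 dB
  at ±10 Hz) that is far simpler to verify than an LMS canceller.
* **Beat screening.** The interactive visual correction of NN intervals
  in laboratory practice is replaced by an automatic rule: intervals
  outside [300, 2000] ms or deviating > 25% from the running median of
  the five preceding intervals are discarded. When an interval is
  discarded, the NN series keeps the terminating beats of the intervals
  that survive, so intervals and beat times stay consistent.
* **SCL integral.** Each sample covers one sample period
  (`sum(x)/fs`), so the integral of a partitioned segment equals the sum
  of the parts' integrals and a constant 5 µS over 20 s integrates to
  exactly 100 µS·s.
* **Extremum amplitudes.** The "normalized signal" for features 11–13
  is the within-segment z-score. An extremum's amplitude is the
  excursion from the preceding opposite extremum (the first extremum is
  measured from the segment's first sample); minima are reported as
  positive drops, and the 0.05 µS threshold applies to both signs.
* **Baseline correction.** EMG block changes always subtract the 2 s
  pre-block envelope mean. SCL and HRV features follow their printed
  formulas by default; optional fixation-referenced correction of the
  level-type features is available (`scl_baseline_correct`,
  `hrv_baseline_correct`) for sensitivity analyses.
* **Ties and degeneracies.** Wrapper selection breaks score ties by
  canonical feature order and never returns an empty subset; all-equal
  block values z-score to zeros; constant feature columns are excluded
  from reduction (undefined correlation) with a warning; empty
  subgroups are emitted with a warning and skipped downstream.
* **SVM settings.** Cost 1 and kernel width 1/d by default. A 3 × 3
  log-spaced grid search over cost and width, scored by inner LOSO on
  the training subjects of each outer fold, is available via
  `svm_params(tune = TRUE)`; it multiplies runtime roughly ninefold and
  is therefore off by default. The grid is scored once per outer fold
  on the full candidate set rather than inside every wrapper step.
* **Reproducibility.** Every stochastic step flows from one integer
  seed through fixed substreams (per subject, per channel), so a
  channel subset reproduces the corresponding channels of a full
  synthesis byte for byte, and rerunning a pipeline configuration
  reproduces every artifact.

## Problem sizes used by the tests

The test suite exercises full-size designs where the quantity under
test depends on them and scaled-down cohorts elsewhere: cohorts of 12
subjects (EMG at 600 Hz) for pipeline mechanics, 100 subjects × 100
replicates (SCL channel only) for the age-effect recovery, one
100-subject default cohort for the five-class chance-exceedance and
permutation-null checks, and 20 replicates of 60-subject cohorts (EMG
at 600 Hz) for the gender × condition subgroup directions. The
replicate-level checks classify without wrapper selection: chance
levels and injected-effect directions do not depend on the wrapper, and
the wrapper itself is verified separately on constructed fixtures.
Sampling rates are configurable; defaults are EMG 1000 Hz, SCL 32 Hz,
BVP 128 Hz.

## Known limitations

* The per-fold wrapper with an inner LOSO scorer is the non-leaky
  reading of one reported selection set per classification; a single
  selection pass on all data would leak the held-out subject into
  selection and is deliberately not offered.
* Frequency-domain HRV is out of scope (20 s blocks are too short for
  valid spectral estimates), as are per-picture event-related SCR
  decomposition, EEG, and real-time use.
* Accuracy differences between subgroups are reported, not tested
  inferentially; subgroup sizes in realistic cohorts are too uneven for
  well-powered comparisons.
* The synthetic generator's block-level lability is log-normal and
  independent across channels; real psychophysiological lability is
  correlated across systems.
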