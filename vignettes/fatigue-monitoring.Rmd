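---
title: "Detecting and predicting localised muscle fatigue from sEMG and elbow kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and predicting localised muscle fatigue from sEMG and elbow kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgfatigue)
```

## The model

Localised muscle fatigue during a sustained isometric contraction is
treated as a three-stage process: **Non-Fatigue**, where the fresh
muscle holds the task posture; **Transition-to-Fatigue**, where new
motor units are recruited (firing rate rises, so myoelectric power
rises) while conduction velocity begins to fall (so the spectral
content shifts downward); and **Fatigue**, where force output can no
longer be maintained. The practical value lies entirely in detecting
the *onset of the transition*: from it, the time of fatigue onset can
be predicted, rather than merely detected after the fact.

The pipeline couples two information streams:

* **sEMG** (two channels on the biceps brachii, 1,000 samples/s)
  carries the detector's input. Per 1 s window, Welch's method
  estimates the power spectral density; the *instantaneous median
  frequency* (IMF) is the frequency splitting the spectral power into
  equal halves, and the *total band power* integrates the density over
  10–499 Hz. The **1D-spectro** composite feature is
  `norm(band power) − norm(IMF)`: since power rises and IMF falls with
  fatigue, the feature increases after transition onset under any
  monotone common scale. This deduction fixes the sign of the
  subtraction, which the source description leaves implicit.
* **Goniometer** elbow angle (degrees, same clock) supplies ground
  truth through a six-rule fuzzy labeller on two kinematic criteria:
  the absolute deviation of the window-mean angle from the 90° task
  posture, and the angular oscillation (within-window standard
  deviation). Rising oscillation is a precursor of fatigue; large
  sustained deviation is fatigue itself. The labeller is used to train
  the detector and to score it, never as the deployed detector.

The detector is a two-class Fisher discriminant $y = w^\top x + w_0$
with $w \propto S_w^{-1}(\mu_{TTF} - \mu_{NF})$ and the threshold at
the midpoint of the projected class means (equal priors). Windows
labelled Fatigue are excluded from training and scoring: the
discriminant's job is only to separate the two pre-fatigue states.

Prediction: the first debounced run of Transition-to-Fatigue
predictions marks the onset $t_{on}$; the predicted fatigue time is
$t_{on} + \bar d$, where $\bar d$ is the mean of the subject's
training-trial transition durations (first Fatigue label minus TTF
onset, per trial).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| window / hop | 1 / 1 | s | ~1 Hz feedback cadence of the status LEDs; non-overlapping keeps windows independent |
| band-pass | 1–499, order 5 | Hz | the acquisition software's dual-pass Butterworth; 500 Hz sits at Nyquist and is clamped to a realisable edge |
| Welch segment / overlap | 256 / 0.5 | samples / – | ~3.9 Hz resolution with ~6 averages per 1 s window; standard for 1 kHz sEMG |
| power band | 10–499 | Hz | lower edge matches the hardware band-pass of the original amplifier |
| normalization | expanding z | – | power (units²) and frequency (Hz) are incommensurable; a causal expanding z-score is streaming-safe. Alternatives: `baseline` (first K windows), `none` |
| memberships d1, d2, d3 | 5, 10, 20 | ° deviation | published membership shapes are graphical only; these are package defaults, config-exposed |
| memberships s1, s2 | 1, 3 | ° std | same |
| persistence | 3 | windows | debounces isolated misclassifications; 1 recovers the literal "as soon as detected" behaviour |

Normalization caveat: the causal expanding z-score makes the feature
scale-stable and guarantees streaming/batch equivalence, but it dilutes
the *within-stage* trend (a step change is progressively absorbed into
the running mean). The feature's increase across the transition
boundary holds under the default; the strictly positive within-stage
slope is guaranteed under the `baseline` mode, and the tests check each
claim under the mode that carries it.

## The synthetic generator: what it emulates, what it does not

No recordings are deposited, so trials are synthesised. A stated world,
chosen once:

* **Timeline** — 180 s trials, transition onset at 55 s, fatigue onset
  at 174 s (the reported mean time-to-fatigue is 174.2 s and accuracy
  is reported high "up to 55 seconds"); subjects are 2 training + 1
  testing trials with ±5 s uniform jitter on the transition and fatigue
  onsets, since real trial durations differ slightly.
* **sEMG** — random-phase harmonic-comb synthesis (the spectral
  representation of a Gaussian process): 60 equal-power sinusoids span
  [0.6, 1.4]× the programmed median frequency, each frequency-modulated
  so the comb's median follows the programmed trajectory — 95 Hz while
  fresh, declining linearly to 60 Hz at fatigue onset (a typical
  fresh-to-fatigued biceps decline). RMS is stepped per stage,
  ×1.4 during the transition (recruitment), ×1.1 in fatigue (power
  falls again as conduction velocity is lost). Channels differ by
  phases and a sub-line comb shift, making them uncorrelated;
  everything is sub-seeded from one master seed, so output is
  bit-identical per configuration.
* **Angle** — white Gaussian oscillation whose standard deviation steps
  from 0.5° to 4° across a 5 s ramp at transition onset; the mean angle
  sags rapidly by 8° at the transition (putting the trace firmly in the
  labeller's transition region within a window), drifts at 0.05°/s, and
  collapses at 20°/s after fatigue onset (crossing the labeller's
  Fatigue region within a window, saturating at 60° deviation — the
  arm drops and the task is abandoned).

Deliberately *not* modelled: motor-unit action-potential shapes and
their superposition statistics, motion artefacts, electrode lift,
amplifier noise, physiological tremor spectra (the oscillation is white
noise, adequate for rolling-std statistics but not for tremor spectral
analysis), inter-subject variability in spectral shape, and non-linear
or non-monotone fatigue progressions. Consequently a green end-to-end
test establishes that the pipeline's machinery — filtering, spectral
estimation, labelling, discrimination, onset timing — recovers a world
whose statistical structure matches the stated qualitative physiology;
it does not establish classification accuracy on real muscles.

## Numerical choices

* **Butterworth design** is done from the analog prototype poles via
  the bilinear transform with pre-warping (verified in development
  against an independent reference implementation to machine
  precision). Zero-phase filtering uses odd reflection padding; the 1 Hz
  high-pass uses a pad of 3 time constants (3·fs/f_c samples) so edge
  transients decay below measurement tolerance.
* **Clamping**: an upper band edge at or above Nyquist is clamped to
  0.99× Nyquist with a warning rather than an error, preserving the
  intent of a 1–500 Hz passband at fs = 1,000 Hz.
* **Median frequency** interpolates linearly on the cumulative
  trapezoidal power. For spectra with a power gap (two separated
  tones) the median is ill-conditioned — any point of the gap splits
  the power — so tests assert the in-gap location and cumulative
  symmetry, not a unique value.
* **Degenerate windows** (zero spectral power) yield `NA` feature
  values, flagged, not an error; the discriminant drops non-finite rows.
* **Singular covariance** in the LDA triggers an escalating ridge
  (recorded in the model) rather than failure.
* **Ties**: defuzzification ties resolve toward the more fatigued
  class, and the discriminant's $y = 0$ boundary maps to
  Transition-to-Fatigue — both safety-first choices for a warning
  device.
* **Standard deviations** use the sample (n−1) convention throughout;
  this is what reproduces the published summary rows (3.22, 2.30)
  exactly.

## Open design points decided here

* The angle deviation is symmetric, `|angle − 90|`; the physical task
  makes downward drift typical, but symmetry covers both directions of
  failure within the 0–180° goniometer range.
* The goniometer channel is used unfiltered (only windowed statistics
  are taken from it).
* The feature dimension equals the sEMG channel count (2 by default);
  training pools the subject's training trials, never across subjects.
* The published aggregate prediction error of 4.35% equals the mean of
  the per-subject error percentages; the alternative derivation from
  the aggregate seconds (7.4/174.2 = 4.25%) is close but not identical.
  The implementation follows the per-subject mean.
* The deployed RED trigger defaults to the fuzzy labeller's Fatigue
  when a goniometer is present (evaluation setting); a classifier-only
  mode triggers RED at the predicted fatigue time for deployments
  without the goniometer.

## Known limitations

* Membership breakpoints are package defaults, not recovered constants;
  accuracy against differently-shaped memberships is untested.
* The synthetic world is deliberately easy for the detector (clean
  step/ramp structure); the ~99% synthetic test accuracy therefore
  exceeds the ~85–90% reported on real muscles and should be read as a
  machinery check, not a performance claim.
* The streaming contract is causal at window granularity; sub-window
  latency (filter group delay in a true real-time system) is out of
  scope because the zero-phase filter is inherently offline per window.
* Prediction rests on the assumption that a subject's transition
  duration is stable across sessions; the jitter study probes ±5 s
  perturbations only.
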