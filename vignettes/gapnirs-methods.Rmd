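---
title: "Models and methods behind gapnirs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gapnirs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapnirs)
```

gapnirs implements a combined behavioral + neurophysiological analysis of
driver interactions with autonomous (AV) and human-driven (HV) vehicles at
unsignalized intersections: a psychometric model of gap acceptance, an fNIRS
preprocessing chain, a nested cross-validated decoder of the interaction
partner, and accuracy-weighted group effect-size maps. This vignette is the
package's account of the science: the models, their assumptions, the
parameters that matter, and the design choices made where the design was
genuinely open. Every empirical statement here is computed by the package's
own test suite or acceptance script.

## The gap-acceptance model

A driver waiting to turn left faces a stream of oncoming vehicles; each
successive pair of vehicles offers a *gap* — the time between their passages.
The probability of accepting a gap of $X$ seconds is modelled by a
two-parameter logistic,

$$P(X; m, w) = \frac{1}{1 + \exp\!\big(-2\ln(1/0.05 - 1)\,(X - m)/w\big)},$$

with $m$ (s) the 50% acceptance threshold and $w$ (s) the distance between
the 5% and 95% points. The slope constant $2\ln 19$ is what ties $w$ to that
5–95% span: $P(m) = 1/2$ and $P(m \pm w/2) = \{0.95, 0.05\}$ identically.
Psychologically, $m$ is the safety margin a driver demands and $w$ the
(un)certainty of the decision — a narrow $w$ means a sharp, consistent
criterion.

```{r anchors}
gap_acceptance_prob(c(3.09, 3.09 + 0.65 / 2, 3.09 - 0.65 / 2), m = 3.09, w = 0.65)
```

**Fitting.** The model is exactly a logistic regression in gap size
(slope $b = 2\ln(19)/w$, intercept $a = -bm$), so `fit_psychometric()`
obtains the maximum-likelihood estimate from `stats::glm(binomial)` and
transforms the coefficients; a direct optimisation of the Bernoulli
log-likelihood is kept in the test suite as an independent oracle. The fit
acts on raw accept/reject events — the 0.35 s binning of
`bin_acceptance()` is for display only, since binning discards information
(a binned-fit comparison is possible by fitting the binned table, but the
raw-event fit is canonical). Guess and lapse rates are fixed at zero: the
model has none, and a driver who must eventually turn has no stimulus-
independent lapse process in this task.

**Uncertainty.** Confidence intervals come from a nonparametric bootstrap
over events (default 1,000 resamples, 2.5–97.5 percentiles). A Bayesian fit
(as psychophysics toolboxes commonly provide) would be an alternative with
the same parametrisation; the bootstrap was chosen because it is assumption-light,
fully reproducible from a seed, and its coverage is directly checkable by
simulation — the suite verifies ≥ 85% empirical coverage at 95% nominal over
200 simulated replicates (400 events, 150 resamples each, sizes chosen to
keep the whole check around a minute). Complete separation (all accepted
gaps above all rejected) leaves the slope unbounded; the fit is returned
with a `separated` flag rather than an error, because separation is a real
outcome of narrow-width drivers at small samples.

`compare_psychometric()` reports parameter differences and CI overlap only;
no p-value is claimed, since overlap of independent bootstrap intervals is
not a calibrated test.

## The synthetic experiment

The generator reproduces the study conditions so that every downstream stage
can be validated with known ground truth.

**Traffic streams.** Each intersection presents 8–10 cars. The first 4–6
gaps are drawn uniformly from 1–3 s — small gaps first, so every driver's
minimal acceptable gap gets probed — and exactly one large gap (3.5–6 s,
uniform) is placed at a position drawn from 5–10 (clipped to fall after the
small run and inside the stream; the configured range may legally reach the
end of the stream, where the large gap is the last opportunity). Each car is
independently labelled AV with probability 0.15; a fixed seed provides the
fixed-sequence variant in which all simulated participants see the same
streams. Field gap distributions are approximately lognormal with mode near
2 s; a truncated-lognormal mode is available, but the uniform-in-range
construction is the default because the experimental design itself is built
from ranges. Oncoming speed is 14 m/s (50.4 km/h, the urban limit the design
assumes).

**The driver.** `simulate_intersection()` walks the gaps in order and
accepts each with the psychometric probability of the matching condition,
stopping at the first acceptance; a driver who rejects everything turns
after the last car (flagged — this is rare under the default profile, as in
the real task). The default profile uses the cohort-level parameters
$m_{AV} = 3.09$, $w_{AV} = 0.65$, $m_{HV} = 3.08$, $w_{HV} = 4.17$ s.
The default protocol is 10 blocks × 10 intersections, with intersections
spaced 30 s apart (the study's ~5:30 min blocks of ten); the accelerator
press for an accepted gap is placed at the moment the leading car of that
gap passes.

**fNIRS forward model.** `simulate_fnirs_recording()` builds, per channel,
ground-truth HbO/HbR concentration time courses: a boxcar per trial
convolved with a double-gamma HRF (peak delay 6 s, configurable), with the
HbR response negative-going and the AV response deepened by
`effect_amplitude` (default 0.2 µmol/L) on the designated effect channels
only. Because the analysis window is anchored at the accelerator press while
hemodynamics lag the neural events that precede the press (the driver is
evaluating gaps before acting), the boxcar starts `onset_lead` seconds
*before* the trigger (default = the HRF peak delay); this places the
response peak inside the ±2 s decision window. Physiological noise is added
in concentration space: sinusoidal cardiac, respiratory (0.25 Hz), and Mayer
(0.1 Hz) components, slow drift, and white noise. Cardiac pulsation
(~1.2 Hz) cannot be represented at the 1.955 Hz sampling rate; it is
synthesised at its aliased frequency (0.755 Hz), which is where a real
recording would show it. Concentrations are converted to 760/850 nm
intensities by the base-10 modified Beer-Lambert law with the same tabulated
extinction coefficients, 3.5 cm source–detector distance, and DPF = 6 that
the inverse uses. Sparse spike artifacts (Poisson, default 0.05/min so that
a typical run keeps most of its channels, mirroring the ~99/107 channels
surviving QC in comparable datasets) multiply the optical signal by
$e^{\pm a}$ — multiplicative in log space so intensities stay positive.

What the simulator does **not** emulate: motion-correlated baseline shifts,
superficial/scalp hemodynamics (short-separation content), optode coupling
changes over time, serial dependence of driver decisions, and fatigue or
learning effects. Passing tests therefore demonstrate the correctness and
calibration of the pipeline's statistics under its stated noise model — not
that real recordings will decode at any particular accuracy.

## Preprocessing

The stage order is fixed: CV screening → band-pass → spike screening →
Beer-Lambert → epoching → normalization.

- **CV screen**: coefficient of variation, $100\,\sigma/\mu$ per channel and
  wavelength on the *unfiltered* raw data; channels with CV > 20% on either
  wavelength are excluded (strictly greater — a channel at exactly 20% is
  kept). CV is computed per wavelength because a single saturating detector
  corrupts one wavelength first; rejecting on the worst wavelength is the
  conservative reading.
- **Band-pass**: 3rd-order Butterworth, 0.01–0.1 Hz, applied
  forward–backward (`signal::filtfilt`) so the filter is zero-phase and
  epoch timing is preserved. Filtering precedes conversion (it acts on the
  raw optical data); since a 0.01 Hz high-pass removes DC, the filter is
  applied to the fluctuation about the channel mean — in log-intensity space
  for whole recordings, which coincides with linear filtering for the
  percent-level fluctuations of fNIRS but keeps intensities positive around
  spikes. A post-conversion filtering option exists
  (`filter_domain = "concentration"`).
- **Spike screen**: the replacement for manual visual inspection. Robust
  z-scores (median/MAD) of the *sample-to-sample increments* count fast
  discontinuities; channels with more than 5 increments beyond |z| > 5 are
  excluded. First differences make the screen blind to slow hemodynamic
  responses and oscillations — screening the raw amplitude instead would
  reject exactly the channels carrying the strongest responses.
- **Beer-Lambert**: $\Delta OD = -\log_{10}(I/I_{ref})$ per wavelength, then
  the 2×2 extinction-matrix inversion with the Gratzer/Cope coefficients,
  3.5 cm distances from the montage and DPF 6.0 at both wavelengths (the
  instrument specifies neither; 6.0 is the conventional adult-head value).
  $I_{ref}$ is the channel temporal mean by default, so concentrations are
  relative to their own run mean; a `reference = "baseline"` mode uses a
  known baseline sample and gives exact recovery of the forward model, which
  is how the suite checks the round trip at 1e-9 relative tolerance.
- **Epoching**: the decision phase is the 4 s window from 2 s before the
  accelerator press to 2 s after the turn begins; both edges are anchored to
  the press trigger (the turn onset is not separately instrumented, and at
  these timescales the press is the best-defined event). Alignment is
  nearest-sample with a closed window and a constant
  $\lfloor 4 f_s \rfloor + 1 = 8$ samples per epoch at 1.955 Hz; edge-
  clipped epochs are dropped with a warning.
- **Normalization**: HbR is z-scored per channel over the whole run before
  epoching. This matches computing normalization before the train/test
  split; the decoder's PCA/ridge stages are fit strictly within training
  folds, and whole-run z-scoring is a per-channel affine map, so it does not
  move class information across folds. Constant channels z-score to zero.

## Decoding

Every timepoint of an epoch is one sample (8 per trial); the feature vector
is the surviving channels. Trials are balanced by subsampling the majority
HV class to the AV count before any fold assignment.

- **Folding** is stratified by class and *grouped by trial*: all timepoints
  of one epoch share a fold. Folding on raw samples would let a classifier
  score test timepoints from their within-trial neighbours (4 s of
  autocorrelated hemodynamics), inflating accuracy; sample-level folding
  remains available (`group_by_trial = FALSE`) for comparison.
- **PCA reduction** is fit on training data only (train mean, train
  eigenvectors). The first PC is removed — in whole-head fNIRS it is
  dominated by global/motion-linked variance — and PCs with eigenvalue
  < 0.7 are discarded (Jolliffe's relaxation of the Kaiser rule; features
  are z-scored, so the covariance scale is approximately a correlation
  scale and "eigenvalue 1 = one variable's worth of variance" is
  meaningful). If fewer than two PCs survive, the first two post-removal
  PCs are kept with a warning rather than failing the fold.
- **The inner loop** (5-fold on the outer-training trials) searches the
  ridge penalty over 50 log-spaced values ($10^{-4}$–$10^4$) jointly with
  the retained-PC count over nested prefixes (2…K, in eigenvalue order) and
  keeps the pair maximising mean validation accuracy. Ties resolve to fewer
  PCs and stronger regularization (the first maximum in a grid ordered that
  way) — the more parsimonious model. No one-standard-error rule is
  applied; the selection is the plain argmax.
- **Ridge logistic regression** is `glmnet` with `alpha = 0`,
  `standardize = FALSE` (features are PC scores). Model outputs are class
  probabilities; $p \ge 0.5$ is called AV, the tie deliberately going to AV.
- **Metrics**: accuracy is the percent of correctly classified samples,
  $100\,(TP_{AV}+TP_{HV})/(TP_{AV}+TP_{HV}+FP_{AV}+FP_{HV})$; the per-class
  F1 is $2TP/(2TP+FP_{AV}+FP_{HV})$. Both are computed from confusion
  counts and cross-checked in the suite against an independent per-sample
  tally. The headline accuracy is the mean across outer folds and the
  reported SD is the across-fold SD, labelled as such.
- **Chance level**: the empirical chance interval repeats the *entire*
  nested decode on trial-label-permuted data (class sizes preserved; 100
  permutations by default) and reports the 5–95 percentile of permuted
  accuracies. A closed-form binomial interval
  ($50 \pm z\sqrt{2500/n}$ on percent scale) is a cheaper approximation,
  but the permutation version inherits every quirk of the actual pipeline
  (balancing, tuning, grouping) and is therefore the honest null.

The suite verifies: planted-signal epochs decode ≥ 95% while their chance
interval straddles 50%; shuffled labels never exceed the interval; a model
trained on signal scores fresh null data at chance; results are invariant to
channel order and bit-reproducible under a fixed seed. Decoder tests run at
reduced size (32 trials, 12 channels, 100 permutations) to keep the suite in
minutes.

## Group maps

- **Subject t-maps**: the pairing unit for the channel-wise paired t-test is
  the driving block — per block, mean AV epoch amplitude vs mean HV epoch
  amplitude (amplitude = mean HbR over the 4 s window), giving up to 10
  pairs per subject. Blocks pair conditions recorded close in time, which
  cancels slow state drifts that a trial-level two-sample test (also
  provided, `pairing = "trial"`) would absorb into its error term. Blocks
  missing a condition are dropped with a warning; degenerate pair tables
  (zero variance) return t = 0 for identical conditions.
- **Weighting**: $t_{avg}(i) = \sum_n t_n(i)\,Acc(n) / \sum_n Acc(n)$ — a
  convex combination, so each channel's group value lies between the subject
  extremes, and the weighting is invariant to the accuracy scale (percent or
  proportion). Subjects whose QC removed a channel simply drop out of that
  channel's combination with renormalized weights.
- **Effect size**: $|d| = |t_{avg}|/\sqrt{df}$ with the sign of $t_{avg}$,
  and $df = n_{subjects} - 1$ by default (the group map is one observation
  per subject reduced to a weighted mean; both df and the squared variant
  $t_{avg}^2/df$ are configurable). The square-root form is the standard
  t-to-d conversion and yields d values in the conventional 0.8–1.2
  moderate-to-large band for plausible group t's; the squared form is
  exposed but not the default.
- **Reporting**: `channel_report()` lists channels at |d| ≥ 0.8 with their
  10–20 emitter–detector labels, sorted by |d|. Projection to MNI space or
  Brodmann areas is out of scope — maps stay in channel space.

Calibration, checked in the suite: on 12-subject synthetic cohorts with a
planted HbR difference, the planted channels exceed |d| = 0.8 and the 95th
percentile of null channels; with no effect, the fraction of channels
reaching |d| ≥ 0.8 stays within 5% across 100 simulated cohorts (cohorts
use reduced per-subject trial counts to keep the check fast).

## Known limitations

- The synthetic noise model is stationary and sinusoidal; real systemic
  physiology is nonstationary and partially task-locked, which can inflate
  decoding in ways the simulator cannot reveal. Short-separation regression
  and motion-correction algorithms (TDDR, spline) are deliberately out of
  scope.
- The psychometric comparison reports CI overlap, not a formal test of
  parameter equality.
- At the study's 15% AV fraction, small protocols yield very few AV
  acceptances; decoder examples and tests therefore raise the AV fraction
  or pool more intersections. The generator's default remains 15%.
- HbO is converted and carried through but not analysed; the analysis path
  is HbR by design (less contaminated by systemic artifacts).
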