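---
title: "Unsupervised neural voice activity detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised neural voice activity detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neurovad)
```

## The problem

Speech brain-computer interfaces are normally trained with supervision: the
neural recording is aligned to a simultaneous acoustic recording, and the
acoustic voice activity provides frame-level labels. For people who can no
longer produce audible speech — late-stage ALS, locked-in syndrome — that
alignment does not exist. `neurovad` implements an acoustic-free
alternative: locate speech-production segments in unlabeled multichannel
ECoG recordings by clustering the time series itself, convert the clusters
into speech/non-speech labels by exploiting the experiment design, train
frame-wise classifiers on those estimated labels, and run them in a
streaming pipeline whose output is frame-identical to offline inference.

The experiment design this targets is a cued single-word reading task: a
word is shown for 2 s, followed by a 3 s inter-trial interval, with roughly
100 trials per session and one session per recording day. Average spoken
word duration is about 1.2 s, so most session time carries no speech — the
asymmetry the label-inference step relies on.

## Feature extraction

Raw signals (1 kHz, two electrode grids) are processed causally:

1. bad channels are dropped and each grid is common-average referenced
   (CAR) independently;
2. a causal 4th-order Butterworth band-pass extracts the high-gamma band
   (70–170 Hz), and a causal 4th-order band-stop (118–122 Hz) attenuates
   the first line-noise harmonic;
3. log band power is computed on 50 ms windows advanced by 10 ms:
   frame *i* covers samples `[i*shift, i*shift + window)` (half-open,
   0-based) and exists once its last sample does, giving
   `T = floor((n - window)/shift) + 1` frames;
4. features are z-scored per day against a calibration (syllable-task)
   segment, population convention, standard deviations floored at 1e-6.

Two numerical choices matter for the package's core contract. Filtering is
strictly forward — no zero-phase second pass — because the streaming
pipeline can only ever filter forward, and the offline and streaming paths
are required to agree on every frame. Both filters are realized as
second-order-section cascades with explicit per-channel state, so chunked
filtering is bit-identical to whole-signal filtering. And the window power
of a completed frame is computed by one shared function in both paths, so
the offline/streaming identity is structural rather than approximate. The
floor inside the log is `1e-10` (silent windows).

Classifiers without temporal memory receive context stacking: each frame is
concatenated with the frames 50, 100, ..., 300 ms in the past (lags 0, 5,
..., 30 at the 10 ms shift — non-overlapping windows). Out-of-range lags
are zero-filled, which in z-scored space equals padding with the baseline
mean.

## Toeplitz inverse covariance-based clustering

Speech localization uses TICC: each of K clusters is a Gaussian Markov
random field over the (optionally multi-layer) observation, parameterized
by a mean and a sparse precision matrix constrained to be block-Toeplitz in
its w × w layer blocks (cross-lag dependencies are time-invariant).
Fitting alternates:

* **Assignment (E)**: the label path minimizing
  `sum_t NLL(x_t; Theta_{c_t}) + beta * (# label switches)` by a forward
  dynamic program with backtracking, ties toward the lower cluster index.
  With `beta = 0` every frame is assigned independently; large `beta`
  forces a single segment.
* **Update (M)**: per cluster, the mean of assigned frames and the
  precision solving the graphical lasso
  `-log det Theta + tr(S Theta) + lam ||Theta||_1,off` over symmetric PD
  block-Toeplitz matrices, by ADMM: an eigenvalue-based proximal step for
  the log-det term alternating with group-averaging over Toeplitz
  equivalence classes plus soft-thresholding (the exact proximal operator
  of the L1 term restricted to the Toeplitz set; the group structure makes
  the two commute into one closed form).

ADMM uses penalty `rho = 1`, absolute/relative tolerances 1e-6/1e-4 and an
iteration cap of 1000; non-convergence is an error, not a silent result.
Empirical covariances get 1e-6 diagonal loading. The returned precision is
the Toeplitz-feasible ADMM iterate, nudged by at most a diagonal shift of
1e-8 onto the PD cone, so its symmetry/Toeplitz structure is exact and its
sparsity pattern has true zeros.

**Objective and penalty scaling.** `fitTICC` reports
`J = sum_t NLL + beta * switches + lam * sum_k ||Theta_k||_1,off`. For this
J to be non-increasing under the alternation, the per-cluster graphical
lasso must be solved with penalty `2*lam/n_k` (cluster size `n_k`): then
the M-step exactly minimizes J for fixed labels, and the E-step exactly
minimizes it for fixed parameters. `mstepUpdate` exposes the unscaled
problem (its `lam` is applied as given); `fitTICC` passes the scaled value
(`scaleByCluster = TRUE`). One deliberate exception to descent exists: when
a cluster falls below the minimum size (`max(20, w*C/10)` frames), the
worst-fitting 1% of frames are reassigned to it and fitting continues —
the standard EM restart trick, keeping K fixed. Such restarts can raise the
objective; they are recorded on the model (`objectiveTrace()` marks them)
and five consecutive restarts abort with an error. Convergence is a
stationary assignment (or `maxIter = 100`).

Initialization is a K-component full-covariance Gaussian mixture (hard
assignment), seeded and deterministic; model selection is bypassed because
K is fixed by design (K = 2: speech vs non-speech). Degenerate mixtures are
retried with shifted seeds, boundedly.

Defaults are `K = 2`, `beta = 50`, `lam = 11e-4`, one layer. Multi-layer
models space their layers 5 frames apart (the dilation), skipping the
40 ms overlap between adjacent windows: 5 layers reach 200 ms, 7 layers
300 ms into the past.

## From clusters to labels

Clusters are unlabeled. Because most session time carries no speech, the
cluster with the *smaller total assigned duration* is taken as speech
(`inferClassMap`). "Length of a cluster's subsequences" could also be read
as mean run length; total duration directly implements the majority-time
rationale and is the default, with `rule = "meanRun"` available. Exact
ties resolve to the lower cluster index with a warning; a single-cluster
assignment maps to non-speech with a warning. No post-hoc merging of
neighboring speech segments is applied.

## Classifiers

Three frame-wise classifiers consume the features:

* **L1 logistic regression** (glmnet), on 7-frame stacked input.
  `l1Strength` is the inverse regularization strength; the glmnet penalty
  is `1/(l1Strength * n)`. Class weighting is off by default.
* **LeNet-like CNN**: the stacked frame is a channels × lags (C × 7) map;
  two 3 × 3 same-padded convolutions growing the feature maps by 32 each,
  each followed by 2 × 2 stride-2 max pooling (floor), then dense layers
  of 128 and 64 units and a softmax head; tanh activations throughout;
  Adam at 1e-4 for 10 epochs. The head has a configurable number of output
  units (default 2); units beyond the first two receive no targets and
  take no part in the class decision.
* **LSTM RNN**: two LSTM layers of 100 units and a linear 2-unit head on
  *unstacked* frames; cross-entropy; Adam at 3e-4 for 20 epochs; truncated
  backpropagation through time with k1 = k2 = 50 frames (0.5 s), hidden
  state carried detached across chunks; the weights of the epoch with
  minimum validation loss are kept.

The neural networks are implemented in base R matrix algebra inside the
package (forward, backprop, Adam); sizes are small enough that BLAS-backed
matrix products carry the load. Training is deterministic given the seed.
Output layers are zero-initialized, which stabilizes the softmax head and
makes label symmetry exact: swapping the training classes exactly swaps
the predictions.

`predictOffline` is implemented as a fold of the identical single-frame
forward pass used by `predictStep` (ring buffer of past frames for the
stacked models, hidden state for the RNN), which is what makes the
offline/streaming frame identity a structural property.

## Evaluation

* **Alignment error** `= 10 ms × Levenshtein distance` between predicted
  and reference frame labels — a timing error that, unlike accuracy, also
  prices temporal shifts. It is a true metric; for equal lengths it is
  bounded by 10 × the Hamming distance.
* **Detection / false-alarm probabilities**: TP/(TP+FN) over reference
  speech frames and FP/(FP+TN) over reference non-speech frames; empty
  denominators are reported as NA, never 0.
* **Per-trial scoring**: each trial is scored on
  `[cue onset, next cue onset)` so both missed speech and spurious
  detections in the inter-trial interval are penalized (the trial window
  is otherwise under-determined). A trial is majority-detected iff
  strictly more than 50% of its reference speech frames are predicted
  speech; not detected iff none are. Trials with error above the mean
  reference speech duration are counted but never removed from the stored
  per-trial errors.
* **Leave-one-day-out cross-validation**: each day serves once as test
  set; the next remaining day is the validation set; each day is z-scored
  against its own calibration segment; training labels come from TICC,
  from the reference VAD, or from a permuted-label control; evaluation is
  always against the reference. A designated development day can be
  excluded throughout.
* **Grid search** over (beta, lam) fits TICC per grid point on a
  calibration session and minimizes the median per-trial alignment error.
* **Channel contributions**: per channel pair, the absolute difference of
  the two clusters' precision entries on the within-time (lag-0) block;
  the same-electrode term is the channel's contribution, the sum over all
  other electrodes its total interdependency; cross-lag blocks are
  reported separately. At desk-scale cluster sizes the unregularized
  precision differences are noisy, so the recommended workflow re-estimates
  the two MRFs at fixed labels with `mstepUpdate` at the standard
  graphical-lasso rate `lam = sqrt(log d / n)` before reading the map.
* **Reference VAD**: an energy-based surrogate for an acoustic VAD — audio
  resampled to 16 kHz, framed on the same 50 ms/10 ms grid, trailing
  5-frame mean of log energy, threshold at the 20th-percentile noise floor
  + 10 dB, capped at −20 dBFS so sustained loud signal is always detected.

## The synthetic generator

All tests run against synthetic sessions with known ground truth
(`generateRawSession`, `generateFeatureSession`). The raw-signal model
emulates, per day: 1/f background noise per channel plus a per-grid
common-mode component (so CAR does real work), a 120 Hz line-noise
harmonic with random phase, per-channel multiplicative day gain drift
(log-sd 0.05), a speech-free 30 s calibration segment, and cued trials
(2 s cue + 3 s ITI; speech onset = cue + 0.3 s + U(0, 0.4) s; duration
truncated-normal with mean 1.2 s, sd 0.25 s, floor 0.3 s, quantized to the
10 ms grid so the labels reconstruct the trial table exactly). During
speech, band-limited (70–170 Hz) bursts are injected on a designated
channel subset: a shared plus private carrier, multiplied by a
syllabic-rate (~4 Hz) log-normal amplitude modulation that is itself
partly shared and partly channel-private. The modulation is what gives
speech frames a full-rank block of conditional dependencies in
window-power space — the structure the cluster MRFs pick up; a purely
shared modulator would collapse that block to rank one and leave almost
nothing in the precision matrix. Amplitudes are calibrated so z-scored
speech-channel features have means around 2–5 and variance ratios around
2–5, the ranges typical of selected productive speech electrodes; the
per-channel loading spread is small (log-sd 0.15) because the emulated
channel set corresponds to electrodes selected for strong activation.

Two aspects of real data are deliberately modeled as misalignment rather
than noise: the neural modulation *leads* the acoustic interval by 150 ms
(`neuralLead`) — articulation precedes phonation — which is the systematic
error floor of clustering-derived labels against an acoustic reference,
and what makes the reference-trained condition beat the TICC-trained one
in cross-validation. The 48 kHz audio surrogate is white-noise bursts
aligned to the acoustic intervals; only envelope timing matters for the
reference VAD.

What the generator does *not* emulate: real cortical geometry and
electrode neighborhood correlation structure, non-stationary noise floors
within a session, articulatory variability across words, movement or
acoustic-contamination artifacts. Passing tests therefore demonstrate the
correctness and the qualitative behavior of the method, not clinical-grade
performance numbers; the absolute error levels on synthetic sessions are
far below those achievable on real recordings.

## Problem sizes used in tests

The test suite and the acceptance script run at desk scale, chosen to keep
each property identifiable: DP-vs-exhaustive checks at T ≤ 12, K ≤ 3 (200
instances); alignment-error oracle on 1000 random pairs of length ≤ 200;
cluster recovery at T = 25 000 frames, C = 16, with disjoint-support
precisions; cross-validation on 4 synthetic days of 8 trials each (16
channels, RNN at 3 epochs); channel-contribution recovery on 10 seeded
25-trial sessions; streaming identity on a 5-trial session under three
chunkings for all three architectures. The vignette-level defaults of the
generator (100 trials, 64 channels) describe the full study conditions.

## Known limitations

* Grid-wise CAR makes a full grid's channels sum exactly to zero, so
  raw-sample covariances of complete grids are rank-deficient; the
  log-power transform removes the exact singularity but CAR still leaks a
  fraction of burst energy into every same-grid channel. The study design
  (selecting a strong subset of a larger grid) avoids the worst of this;
  analyses on very small grids should select a channel subset.
* The GMM initialization uses a seeded subsample for its hierarchical
  start; different subsample sizes can change the TICC fixed point on
  hard problems.
* The empty-cluster restart keeps K fixed but breaks monotone descent at
  the restart iteration (recorded on the model).
* `mstepUpdate` errors rather than degrades when ADMM does not converge
  within its cap.
* The RNN architecture is fixed at 2 × LSTM-100 + linear-2; the printed
  parameter-count folklore for such models varies by convention and is not
  asserted anywhere.
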