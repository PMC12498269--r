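# neurovad

Unsupervised voice activity detection from multichannel neural recordings.

## The problem

Speech brain-computer interfaces are usually trained with supervision: the
neural signal is aligned to a simultaneous microphone recording, whose
acoustic voice activity supplies frame-level speech/non-speech labels. For
people who can no longer produce audible speech (late-stage ALS, locked-in
syndrome) no such alignment exists. `neurovad` implements an acoustic-free
training path for neural voice activity detection (nVAD):

1. **Locate** speech-production segments in unlabeled ECoG high-gamma
   (70–170 Hz) log-power features with Toeplitz Inverse Covariance-based
   Clustering (TICC): each cluster is a Gaussian Markov random field with
   mean μ and sparse block-Toeplitz precision Θ, and the assignment
   minimizes

   ```
   Σ_t  NLL(x_t ; Θ_{c_t})  +  β · Σ_t 1[c_t ≠ c_{t−1}]
   ```

   (dynamic program) alternating with a Toeplitz-constrained graphical
   lasso for Θ (ADMM), from a Gaussian-mixture initialization.
2. **Label**: in a cued single-word task most session time carries no
   speech, so the cluster with the smaller total assigned duration is the
   speech class.
3. **Train** frame-wise classifiers on the estimated labels — L1 logistic
   regression, a LeNet-like CNN (7-frame context stacking, 0 to −300 ms),
   and a 2×LSTM-100 RNN (TBPTT, k₁ = k₂ = 50 frames).
4. **Evaluate** with the alignment error (10 ms × Levenshtein distance
   between label sequences), frame-level detection/false-alarm
   probabilities, the majority detection rate (> 50 % of a trial's
   reference speech frames hit), and a leave-one-day-out cross-validation
   harness.
5. **Stream**: a node pipeline (ingest → CAR → band-pass → notch → framer
   → z-score → classifier → emit → log) with explicit per-node state whose
   per-frame decisions are bit-identical to offline inference under any
   chunking of the sample stream.

A synthetic session generator (cued trials, band-limited bursts on a
speech-channel subset, line noise, day gain drift, aligned audio
surrogate) provides ground truth for every stage; no external data is
required. A thin command-line wrapper lives in `inst/scripts/nvad`.

## Worked example

Generate one synthetic day, extract features, cluster, and score the
estimated labels against the ground truth:

```r
library(neurovad)

cfg <- sessionConfig(nChannels = 16, nGrids = 2, nTrials = 12,
                     baselineDuration = 10,
                     speechChannelSet = c(2, 5, 9, 14), seed = 7)
ses <- generateRawSession(cfg)
rec <- preprocessRaw(ses$recording)          # per-grid CAR
fr  <- extractHGPower(rec)                   # causal 70-170 Hz log power
base <- FrameSequence(frameValues(fr)[1:995, ],
                      channelIds = channelIds(fr))
fz  <- applyZscore(fr, fitBaselineStats(base))

fit <- fitTICC(fz, ticcHyperparams())        # K = 2, beta = 50, lam = 11e-4
fit$model
#> TICCModel: K = 2 clusters, 2 iterations, converged: TRUE
#>   beta = 50, lambda = 0.0011, layers = 1, dilation = 5 frames
#>   objective: 162644.1241 -> 162352.7045
#>   cluster 0: 5410 frames
#>   cluster 1: 1586 frames

map  <- inferClassMap(fit$labels)            # minority duration = speech
nvad <- relabel(fit$labels, map)
tm   <- trialMetrics(nvad, ses$truth)
median(tm$trialErrors$errorMs)               # 315 (ms)
tm$majorityDetectionRate                     # 1
frameRates(nvad, vadLabels(ses$truth))
#> detection falseAlarm
#>     0.859      0.026
```

The 315 ms median alignment error on this clean synthetic day is mostly
the built-in neural lead: the injected cortical modulation precedes the
acoustic speech interval by 150 ms, so clustering the neural signal
recovers intervals that are systematically early relative to the acoustic
reference — the same mechanism that separates acoustically-supervised from
cluster-supervised training on real data.

Downstream, `trainClassifier()` / `predictOffline()` fit and run the
classifiers, `runLodoCV()` is the cross-validation harness, and
`buildPipeline()` + `pushSamples()` replay a recording through the
real-time path.

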