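---
title: "Methods: sustained-vowel analysis for Parkinson's disease voice classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sustained-vowel analysis for Parkinson's disease voice classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pdvoice)
```

## The problem and the pipeline

Speech is affected in the large majority of people with Parkinson's
disease (PwPD): sustained phonation becomes less stable (higher jitter
and shimmer, lower harmonics-to-noise ratio), pitch control degrades
(slow tremor, transient distortions), and these changes leave visible
signatures in spectrograms of a held vowel. `pdvoice` implements a
complete analysis of sustained-vowel /a/ recordings that discriminates
PwPD from healthy controls (HC), in five stages:

1. **Audio acquisition** — mono 16-bit PCM WAV, either telephone-band
   material (0.3–3.4 kHz, 8 kHz sampling, e.g. voicemail recordings) or
   smartphone material (full band, 44.1 kHz). A synthetic generator
   stands in for clinical data so that every stage is testable offline.
2. **Preprocessing** — amplitude normalization to $[-1,1]$, decimation
   of 44.1 kHz material by a factor of 5 (to 8820 Hz, so one analysis
   model covers both channels), short-time-energy silence trimming,
   selection of the longest continuous voiced segment, and a fixed 1.5 s
   center clip for spectrograms. Recordings shorter than 1.5 s after
   trimming are excluded with reason `too-short`.
3. **Phonation features** — a 23-entry vector: mean/SD of $F_0$, mean/SD
   of formants $f_1..f_4$, HNR, five jitter variants (local, local
   absolute, RAP, PPQ5, DDP), six shimmer variants (local, local dB,
   APQ3, APQ5, APQ11, DDA), and the unvoiced-frame fraction.
4. **Spectral features** — in 256-sample (32 ms at 8 kHz) windows with
   50% overlap, an AR(10) model is fit by the Levinson–Durbin recursion
   on the biased autocorrelation; the LPC coefficients, their log-area
   ratios (LAR), LPC cepstra (LPCC) and mel-frequency cepstra (MFCC) are
   summarized per recording by the mean and sample variance of each of
   the 10 coefficients. Variance vectors combined with the phonation
   vector (10 + 23 = 33 entries) are the strongest feature-based input.
5. **Evaluation** — repeated holdout: 100 random 70/30 subject-level
   splits (one recording per subject, so identities never leak across
   the split), held-out AUC per split; random forest (1000 trees, 6
   candidate variables per split, terminal node size 5) with
   mean-decrease-Gini importance, forward stepwise-AIC logistic
   regression, a transfer-learning style image-classifier head on
   spectrograms, Monte-Carlo Shapley importance, and a Wilcoxon rank-sum
   comparison of AUC distributions (e.g. mel- vs linear-scale
   spectrograms).

## The synthetic-vowel generator

The generator (`synthesizeVowel()`) is a source–filter model whose
parameters are exactly the quantities the estimators later measure:

- **Source**: a glottal pulse train with $-12$ dB/octave spectral tilt
  (two cascaded leaky integrators — a deliberate simplification of the
  LF glottal model; enough to exercise every estimator without
  articulatory modeling). Pulses are placed with fractional-sample
  precision so that sub-sample timing perturbations survive sampling.
- **Jitter / shimmer**: cycle lengths $T_i = (1/f_{0,i})(1+\eta_i)$ and
  amplitudes $1+\xi_i$ with $\eta_i,\xi_i$ i.i.d. Gaussian. If
  $\eta_i \sim N(0,\sigma)$ then $E|\eta_i-\eta_{i-1}| = 2\sigma/\sqrt{\pi}$,
  so $\sigma = (\text{pct}/100)\cdot\sqrt{\pi}/2$ makes the *local*
  jitter estimator recover the nominal percentage in expectation. This
  calibration constant is analytic and frozen.
- **Tremor and distortions**: $f_{0,i}$ is modulated by
  $d\,\sin(2\pi r t)$ (the slow "ripples" visible in PwPD mel
  spectrograms) and by Poisson-distributed transient events that deviate
  $F_0$ by up to ±8% and dip amplitude (motor-block-like distortions).
- **Filter**: cascaded second-order resonators at the /a/ formants
  (700, 1220, 2600, 3500 Hz — F1/F2 are where group differences
  concentrate in average-spectrogram difference maps).
- **Noise**: aspiration noise shaped by the same resonators, scaled so
  the periodic-to-noise power ratio equals the target HNR; the
  autocorrelation HNR estimator then recovers the target by
  construction.
- **Channel**: telephone = zero-phase band-pass FIR (300–3400 Hz,
  Blackman-windowed sinc, ≈74 dB stopband) plus Fourier resampling to
  8 kHz; smartphone = identity at 44.1 kHz. Both quantize to 16 bits,
  round-to-nearest without dither, which keeps cohort generation
  bit-deterministic under a seed.

**The stated cohort world** (`cohortSpec()` defaults): group-mean $F_0$
116/123 Hz for HC/PD males and 192/188 Hz for HC/PD females
(inter-speaker SD 10 Hz); HC draws jitter 0.3–0.7%, shimmer 2–5%, HNR
18–25 dB, tremor depth ≤ 0.4%; PD draws jitter 1.5–4%, shimmer 6–12%,
HNR 8–15 dB, tremor depth 1–4% at 4–7 Hz, with 0.2–1 distortion
events/s. The perturbation ranges follow the clinical voice-analysis
convention that healthy local jitter sits below ~1% and healthy shimmer
below ~4–5%, with pathological voices well above; no quantitative PD
parameter distribution is published for the emulated cohorts, so these
ranges are chosen once for testability (strong, realistic separation)
and not revisited. What the generator does **not** emulate: articulation
and vowel color beyond fixed formants, room acoustics and device
nonlinearities, age/sex vocal-tract scaling, and real inter-speaker
covariance structure. A green end-to-end test therefore establishes that
the pipeline's estimators, features and evaluation machinery work and
recover planted group structure — not that the classifier performance on
real cohorts is reproduced.

## Estimator details and numerical choices

- **Pitch**: frame-based normalized autocorrelation (window $3/f_{min}$,
  10 ms hop, search range 60–500 Hz), lag normalization by the energies
  of the two overlapping segments (exactly 1 for a perfectly periodic
  frame), parabolic peak interpolation for sub-sample lag resolution.
  Octave robustness: among local maxima within 0.02 of the global peak
  the shortest lag wins (all subharmonic lags of a periodic signal score
  equally); a post-pass rescales residual frames sitting near an integer
  multiple of the track median. Voicing threshold 0.45 (0.35 for segment
  selection, where severely aperiodic pathological phonation must still
  count as voice), plus an energy floor of 1% of the maximum frame
  energy.
- **Cycle marks**: waveform matching — each period is the lag in
  $[0.8T, 1.25T]$ maximizing the normalized cross-correlation between a
  cycle-length template and its continuation, refined parabolically.
  Matching whole cycle shapes (rather than picking single peaks, which
  alternates between formant-ringing maxima) is what makes 2% jitter
  recoverable within ±0.5 points at 44.1 kHz.
- **HNR**: per voiced frame, $10\log_{10}(r/(1-r))$ at the pitch lag,
  averaged and capped at +40 dB (the $r \to 1$ limit).
- **Formants**: LPC root-solving (order 12 below ~11 kHz, pre-emphasis
  0.97, 25 ms Hamming frames); candidates need bandwidth < 400 Hz and
  250 Hz < $f$ < Nyquist − 50 Hz. The 250 Hz floor rejects spectral-tilt
  poles; no vowel has $F_1$ below it. Recordings above 12 kHz are
  decimated to 11025 Hz first so that $f_4 = 3.5$ kHz stays inside the
  anti-alias passband.
- **AR features**: biased autocorrelation estimator (guarantees
  $|k_i|<1$ and a stable model), no pre-emphasis, sign convention
  $A(z) = 1-\sum a_k z^{-k}$ throughout. LPCC by the cepstral recursion
  $c_n = a_n + \sum_{k<n}(k/n)c_k a_{n-k}$; LAR as
  $\ln((1+k)/(1-k))$. MFCC: Hann window, 26 triangular unit-height mel
  filters over 0–fs/2, natural-log energies floored at $10^{-12}$,
  orthonormal DCT-II, coefficients 1–10 ($c_0$ excluded, hence exact
  gain invariance).
- **Spectrograms**: linear scale — Hann 1024/75% overlap/NFFT 1024,
  no padding (48 frames for 1.5 s at 8820 Hz), values
  $10\log_{10}(|S|/\max|S|)$; mel scale — Hann 512/90% overlap resolved
  as hop $\lfloor 512 \cdot 0.10\rfloor = 51$ with center padding
  (260 frames), 256 mel filters, log-mel normalized by the maximum.
  The non-integer 90% hop and the padding convention are dialect
  choices fixed by the printed frame counts. Images: values clamped to
  $[-80, 0]$ dB, bilinear resampling to 600×600, viridis colormap
  (perceptually uniform; the colormap id is stamped into the image
  object because downstream CNNs can be sensitive to it), PNG by
  default (lossless and bit-deterministic; JPEG quality 95 available
  for compatibility).

## Evaluation design

- **Splits** are simple random 70/30 at the subject level (matching the
  evaluated protocol's wording); a stratified option exists behind a
  flag. Splits leaving one side single-class are resampled and counted.
- **Random forest** is implemented in compiled code (no RF package is
  available in the target environment): bootstrap-resampled CART with
  Gini splits, `mtry = 6`, terminal node size 5, 1000 trees,
  vote-fraction scores, importance as the per-tree average Gini
  decrease. When fewer than 6 features exist, `mtry` falls back to
  $\lceil\sqrt{p}\rceil$.
- **Stepwise logistic regression**: forward from the intercept-only
  model, adding the AIC-minimizing feature until no addition improves
  AIC; ridge fallback (flagged) under perfect separation.
- **Image classifier**: the transfer-learning recipe — frozen
  convolutional backbone, trainable head of batch normalization, two
  1024-unit ReLU layers, 20% dropout, 2-class softmax, adam at 0.001,
  10 epochs, batch size 4. The pretrained Inception backbone requires a
  network download and is therefore pluggable but not shipped; the
  shipped `tiny-random` backbone is a fixed-seed random convolutional
  feature extractor (two strided 3×3 convolutions + average pooling,
  784 features from 128×128 inputs). Random convolutional features are
  a classical strong baseline; the smoke test establishes that the
  head training machinery learns, not that ImageNet features are
  reproduced.
- **Shapley importance**: Monte-Carlo permutation sampling (random
  feature permutation + random reference row per draw), mean |value|
  per feature across observations; default 100 draws per observation.
- **AUC comparison**: two-sided unpaired Wilcoxon rank-sum on the two
  per-iteration AUC samples. Whether the original mel-vs-linear
  comparison was paired across identical splits is not stated; a paired
  signed-rank option is provided.
- **Permutation controls**: a proper null draws a *fresh* label
  permutation per iteration. A single fixed permutation retains a
  sizeable random association with the feature-space cluster structure
  and its held-out AUC can sit far from 0.5 in either direction; the
  test suite's controls therefore re-permute every iteration.

## Design decisions taken where the protocol was open

- The silence-trimming sentence is ambiguous about whether the energy
  threshold triggers trimming or speech; the only physically sensible
  reading — retain the span between the first and last frame *above*
  threshold (25 ms window, 10 ms hop, 1% of maximum frame energy) — is
  implemented.
- The 23-feature vector is never enumerated; the enumerable set (2 F0 +
  8 formant + 1 HNR + 5 jitter + 6 shimmer) totals 22, and the 23rd slot
  is implemented as the unvoiced-frame fraction, a standard voice-report
  quantity.
- Printed frame counts imply an 8 kHz analysis rate in one place and
  8820 Hz in another; both rates are supported, with 8820 Hz the default
  for decimated smartphone material and 8000 Hz for telephone material.
- Exact numerical parity with any external phonation-analysis tool is a
  validation activity, not a contract: the metric formulas documented
  here, applied to this package's own cycle sequence, are the contract.

## Known limitations

- The generator's group separation is intentionally strong; effect-size
  realism on real cohorts is out of scope.
- Formant estimates above ~3.4 kHz are unreliable for telephone-band
  material (the channel removes the energy); $f_4$ statistics there
  reflect residual band energy.
- The stepwise model-selection path refits `glm` per candidate and is
  quadratic in feature count; it is intended for the ≤ 33-feature
  vectors used here.
- Single fixed label permutations are not a null distribution (see
  above); use per-iteration permutation for controls.
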