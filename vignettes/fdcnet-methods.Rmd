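---
title: "Classifying auscultation sounds with fused convolutional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying auscultation sounds with fused convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdcnet)
```

## The problem

Digital auscultation produces mono audio recordings of lung sounds or heart
sounds (phonocardiograms), each labelled with a diagnosis class — for lungs
typically Bronchiectasis, COPD, Health, LRTI, Pneumonia and URTI; for hearts
Extra Systole, Normal, Noisy Normal, Murmur, Noisy Murmur and an unlabelled
test category. Such datasets are small (hundreds of recordings), severely
imbalanced (a COPD:LRTI ratio of 785:2 in the lung set this pipeline is
shaped around), and variable in length (10–90 s). `fdcnet` implements a
complete classification pipeline for this setting:

1. **augmentation** of the raw audio (not the images) to grow each class
   tenfold,
2. conversion of 3-second windows into three kinds of **128×128
   time–frequency feature images** — STFT spectrogram, MFCC and chromagram,
3. three convolutional classifiers (**FDC-1/2/3**) plus their late-fusion
   combination (**FDC-FS**) that concatenates the penultimate feature
   vectors (64 + 64 + 128 → 256) before a softmax head,
4. training and **support-weighted evaluation**, the appropriate summary
   under class imbalance,
5. a **synthetic data generator** so every stage is testable end to end
   without clinical recordings.

## Augmentation operators

Three operator families act on the waveform; the default dataset policy
applies all ten variants per original, so an augmented dataset holds exactly
eleven files per original recording:

* **Noise mixing** — `y' = (1 − α)·y + α·y_noise` with one
  `α ~ U[0.001, 0.005]` drawn per clip, two independent copies. The noise
  source is unit-variance white gaussian noise by default, or a random crop
  from a user-supplied pool of background-noise clips. Whether α should be
  drawn per clip or per sample is an open reading of the mixing rule; one
  draw per clip is implemented, which keeps the operator a convex
  combination of two fixed signals.
* **Time stretching** — factors {0.5, 0.7, 1.2, 1.5}; a phase vocoder
  (Hann STFT, 4× overlap, magnitude interpolation with phase accumulation)
  changes duration by the inverse factor at constant pitch. Output length is
  fixed to `round(n/rate)` samples, so the duration contract holds exactly.
* **Pitch shifting** — {−3.5, −2.5, 2.5, 3.5} semitones; implemented as a
  vocoder stretch by `2^(−s/12)` followed by resampling back to the original
  length, which scales every frequency by `2^(s/12)` at constant duration.

Two noise copies is the only composition under which 4 stretch + 4 shift +
`noise_copies` variants reach the tenfold policy, and it reproduces the
reference per-class multiplicities (e.g. 46 → 506, 785 → 8,635) exactly;
`augment_dataset` asserts these laws in the test-suite without rendering
audio via `render = FALSE`.

Augmented copies always inherit the split of their original recording, so a
split computed after augmentation can never leak an original into training
and its noisy copy into test.

## Feature images

Each recording is cut into non-overlapping 3 s windows (a trailing window
covering at least half the span is zero-padded, otherwise dropped, so a
T-second clip yields `floor(T/3)` windows plus one when the remainder is at
least 1.5 s). Per window:

* **Spectrogram** — magnitude STFT with a 23 ms periodic Hann frame,
  23 ms hop and FFT size the next power of two (512 points at the default
  22,050 Hz, giving 257 bins × 130 frames).
* **MFCC** — mel filter bank (`mel(f) = 2595·log10(1 + f/700)`, 128
  triangular filters), log, orthonormal DCT-II, first 40 coefficients.
  The band count and coefficient count are package defaults, declared here
  because no canonical values exist for this pipeline. At 128 bands over a
  512-point FFT, the narrowest low-frequency triangles can cover no FFT bin
  center; such filters fall back to sampling their nearest bin so no band
  is silently empty (this is what makes the white-noise sanity property —
  energy concentrated in coefficient zero — hold).
* **Chromagram** — STFT magnitudes folded onto 12 semitone pitch classes
  with A440 reference (rows ordered C…B), octave-equivalent by
  construction.

All three matrices pass through one imaging path:
`pixel = |v| / max|v| × 255`, rounded half-away-from-zero (making the
`{0, M/2, M} → {0, 128, 255}` example deterministic), then bilinear
resizing to 128×128 (EBImage). The map is invariant to positive rescaling
of the input and saturates the global maximum at 255. Images are stored as
lossless PNG; a lossy format would break bit-exact reproducibility tests
for no benefit.

## The architectures

The builders are declarative: an `architecture_spec` is an ordered list of
layer specifications with exact shape inference and parameter accounting,
independent of any training backend. The reference layer tables are
reproduced exactly:

```{r params}
count_parameters(build_fdc1(6))   # 241,174 trainable
count_parameters(build_fdc3(6))   # 362,214 + 1,152 non-trainable
count_parameters(build_fdcfs(6))  # 1,483,958 total
```

Conventions worth recording:

* Pooling stride equals pool size. FDC-1/2 pool with floor (valid)
  semantics; FDC-3 pools with ceiling semantics (61 → 31, 29 → 15,
  13 → 7), which is what its printed shapes require.
* FDC-2's second convolution has 64 filters: its printed weight count
  (18,496 = 64·(3·3·32 + 1)) is authoritative over prose mentioning 48.
* The per-layer final-dense figures printed in some reference tables
  (650/1290) correspond to 10 output units; the builders follow the
  6-class totals, which are internally consistent (and `build_fdc1(10)`
  reproduces 241,434).
* Inputs are single-channel 128×128 images: the first convolution's 624
  parameters (= 24·(5·5·1 + 1)) are only consistent with one channel.
* Batch normalization carries 2 trainable (scale, shift) and 2
  non-trainable (running mean, variance) parameters per channel.
* FDC-FS feeds one shared input image to all three truncated branches and
  is trained end to end from scratch by default; initializing branches
  from separately trained models is the alternative reading of its
  transfer-learning description and can be had by compiling the branch
  models separately — the accounting is identical either way.
* The generic activation in the layer-algebra notation is treated as
  exactly that — generic; the concrete stacks use ReLU and a softmax head.

`count_parameters` is cross-checked in the suite against an independent
brute-force oracle that allocates every weight tensor and counts elements,
on the four shipped architectures and on 100 randomized small ones.

## The training engine

No deep-learning framework exists in this package's dependency footprint,
so training is done by a compact engine inside the package: im2col
convolutions executed as BLAS matrix products with persistent C++
workspaces, exact max-pool argmax backprop, standard batch-norm training
statistics (momentum 0.9, ε = 1e−5), inverted dropout, categorical
cross-entropy with a fused softmax gradient, and Adam (lr 1e−3, β =
0.9/0.999) — the optimizer and learning rate are package defaults, declared
in `train_config` and logged, since no canonical values exist for this
pipeline. Weights initialize He-normal before ReLU and Glorot-uniform
before softmax. The engine's analytic gradients are validated against
central finite differences (relative error below 1e−5) on architectures
exercising every layer kind, including a two-branch fused graph.

Batch-norm running statistics warm up on a cumulative-average schedule and
are re-estimated over the training set (a stats-only forward sweep, no
dropout) before each validation pass, so validation and test always score
the model actually being trained — with only a handful of mini-batches per
epoch, exponentially averaged statistics would otherwise lag the moving
weights badly enough to make early validation meaningless.

Reference training regimes: 50 epochs at batch 64 on original-size
datasets, 30 epochs at batch 128 on tenfold-augmented ones; dropout 0.5
(0.25 inside FDC-3 blocks). `train_config` adds optional scheduling:
validation-loss patience (with best-weight restore), an accuracy plateau
(stop after three consecutive epochs at or above a target validation
accuracy), and reduce-on-plateau learning-rate halving. Class balancing follows the replication reading of minority
oversampling: minority rows of the training index are duplicated with
replacement until all classes match the majority count; validation and
test rows are never touched. Balancing applies to the training feature
index after augmentation and splitting. Accuracy is reported per 3-s
window image; a recording-level majority vote is deliberately not the
default because the reference protocol scores windows.

## Splits

`split_dataset` assigns train/val/test = 64/16/20 by largest-remainder
allocation, stratified per label, deterministic per seed. By default it
groups by source recording so 3-s windows or augmented copies of one
recording never straddle splits; `group_by_source = FALSE` gives a plain
record-level split. Whether the reference protocol grouped by patient is
not knowable from its description, so both behaviors are provided and the
leak-free one is the default.

## The synthetic generator, and what the tests do and do not show

Each synthetic class is a harmonic stack (amplitudes 1/h) on a
class-specific fundamental — six classes log-spaced over 80–1000 Hz —
amplitude-modulated at ~1 Hz for the low-pitched (cardiac-regime) classes
and ~0.25 Hz for the rest (respiratory regime), with additive gaussian
noise (σ = 0.05) and peak normalization. Default durations are 9–12 s so
every clip yields at least three windows while the suite stays fast.

These signals are separable by construction (a nearest-spectral-centroid
baseline exceeds 0.95 accuracy, asserted in the suite), which is the
point: they verify that the pipeline — augmentation bookkeeping, feature
geometry, shape-correct architectures, optimization, evaluation — is
wired correctly. A desk-scale study (120 clips, 20 per class, spectrogram
images reduced to the first window of each clip, grouped stratified
64/16/20 split, batch 8 so the ~76-image training split still yields about
ten gradient steps per epoch, at most 30 epochs with the plateau stop and
learning-rate schedule) must bring every architecture to at least 0.9
support-weighted test accuracy. Passing says nothing about accuracy on
real lung or heart recordings: synthetic classes differ in fundamental
frequency, not in the subtle broadband textures (crackles, wheezes,
murmurs) that make the clinical problem hard, and the reference headline
accuracies (99.1% lung, 97% heart) are obtainable only with the external
clinical datasets, which this package deliberately does not download.

## Numerical choices and degenerate inputs

* WAV I/O is PCM 16/24-bit and float32; 16-bit quantization uses
  symmetric 32768 scaling on write and read.
* Resampling is linear interpolation preceded by a 6th-order Butterworth
  low-pass (zero-phase) at 0.9 of the target Nyquist when downsampling.
* An all-zero feature matrix maps to an all-zero image (the 255
  saturation guard divides only by nonzero maxima).
* A clip shorter than half a window yields an empty window list, not an
  error; a label with fewer records than splits triggers a warning and
  best-effort assignment; a class absent from an evaluation split is
  reported with support 0 and excluded from the averages.
* A single-record split goes to train (largest fraction wins ties).
* All randomness (noise draws, splits, initialization, shuffling,
  dropout) flows through explicit integer seeds via an RNG-state-
  preserving wrapper, so reruns are bit-identical and library calls never
  disturb the caller's RNG.

## Limitations

* The engine is CPU-only, double precision, single-threaded apart from
  BLAS; it is sized for the desk-scale studies above, not for training on
  the full augmented clinical datasets.
* JPG export of feature images is possible downstream but PNG is the
  internal format; pixel-exact equality with a JPG-based pipeline is not
  expected.
* The chromagram uses hard bin-to-pitch-class assignment, not a tuned
  filter bank; leakage between adjacent classes is possible for
  frequencies near class boundaries.
* Crackle/wheeze event segmentation, scalogram features, image-domain
  masking augmentation and pre-trained backbones are out of scope.
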