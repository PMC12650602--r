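---
title: "Dual-branch gated-fusion heartbeat classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch gated-fusion heartbeat classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Beat-by-beat arrhythmia screening assigns every heartbeat in a single-lead
ECG to one of the five AAMI classes: N (normal and bundle-branch/escape
beats), S (supraventricular ectopic), V (ventricular ectopic), F (fusion of
normal and ventricular), and Q (unknown or paced). Two kinds of evidence
matter: local waveform morphology (QRS width, P-wave presence, T-wave
polarity) and longer-range temporal structure within the window (where the
neighbouring beats fall, how activation timing deviates). `hctgnet`
implements a classifier that learns the two kinds of evidence in two
separate branches and fuses them per feature dimension with a learned gate,
together with the entire data path around it: WFDB input, preprocessing,
class balancing, seeded training, evaluation, and an ablation harness.

## Model

The input is one beat window `x` of 188 normalized samples (1.5 s at
125 Hz).

**Convolutional branch.** A stem 1-D convolution (1→64 channels, kernel 7,
stride 1, padding 3) is followed by three residual blocks; each block
computes `y = ReLU(F(x) + W_down x)` where `F` is two kernel-3 convolutions
with batch normalization and a ReLU between, and `W_down` is the identity
when the shape is unchanged or a strided 1×1 convolution otherwise. The
blocks map 64→64 (stride 1), 64→128 (stride 2, halving the 188-sample axis
to 94), and 128→256 (stride 1). Global average pooling over time yields the
morphology feature `c ∈ R^256`.

**Transformer branch.** Each scalar sample is embedded linearly into
`d_model = 128` dimensions and the sinusoidal positional encoding
`PE(pos, 2i) = sin(pos / 10000^(2i/d_model))`,
`PE(pos, 2i+1) = cos(·)` is added. Two post-norm encoder layers follow,
each with 4-head scaled dot-product self-attention
(`softmax(QK^T / sqrt(d_k)) V`, `d_k = 32`), a position-wise feed-forward
network of width 256, dropout 0.1, and residual connections with layer
normalization. Average pooling over the 188 positions yields the context
feature `t ∈ R^128`.

**Gated fusion.** Both features are projected into a shared space of
dimension H = 256 (`c~ = W_c c`, `t~ = W_t t`). A two-layer MLP
(512→256→256, ReLU between) on the concatenation produces per-dimension
gate logits, squashed by a sigmoid to `g ∈ (0,1)^256`, and the fused
feature is the convex combination `f = g ⊙ c~ + (1−g) ⊙ t~`. The gate
decides, dimension by dimension, whether morphology or temporal context
drives the decision.

**Classifier.** `f` passes through a 256→128 layer with ReLU and dropout
0.3, then a 128→5 layer with softmax; prediction is the argmax (ties break
toward the lower class index).

Four variants exist for ablation: `full`, `cnn_only` (the 256-vector `c`
straight into the classifier), `transformer_only` (`t`, classifier input
128), and `concat_no_gate` (`[c~; t~]`, classifier input 512).

## Preprocessing

The chain is: denoise → downsample → segment → normalize.

* **Denoising** removes baseline wander and high-frequency noise while
  preserving P-QRS-T morphology. The filter family is not dictated by the
  task, so it is a design choice: a zero-phase (forward-backward)
  Butterworth pair — high-pass order 4 at 0.7 Hz, low-pass order 3 at
  55 Hz. With the squared response of two passes this attenuates
  everything below 0.5 Hz by more than 20 dB while keeping 1-35 Hz (the
  band carrying the clinical waves) within 1 dB, and the zero-phase
  property moves R peaks by at most one sample. The corners were chosen
  from these band constraints, not tuned to data.
* **Downsampling** 360 → 125 Hz uses Fourier-method resampling (spectral
  truncation at the output Nyquist). This is an exact anti-aliased
  resampler for band-limited content; the common polyphase-FIR
  alternative in the available signal library showed a ~10% passband gain
  error, which would distort amplitudes ahead of normalization.
  Annotation indices are mapped by `round(i * 125/360)` (half-up).
* **Segmentation** cuts `[r−90, r+98)` (half-open, 0-based) around each
  annotated R peak: 188 samples covering the full P-QRS-T complex at
  125 Hz, with the R sample at offset 90. This is the only reading under
  which "90 before + 98 after" sums to 188; whether the R sample is
  counted inside the "after" half is otherwise ambiguous, and the chosen
  convention is asserted in tests. Beats with insufficient context are
  skipped and counted in provenance — padding would fabricate morphology.
* **Normalization** is the per-window z-score `(x − μ)/(σ + 1e-6)` with
  the population (uncorrected) standard deviation; the formula carries no
  Bessel correction and the ε-guard implies a denominator that may be
  exactly zero. Constant windows map to all-zeros.

## Class balancing

Minority classes are oversampled with SMOTE: each synthetic beat is
`x + λ(x_nn − x)` for a uniformly drawn `λ ∈ [0,1]` and `x_nn` one of the
k = 5 nearest same-class neighbours under Euclidean distance (k is SMOTE's
canonical default; classes smaller than k+1 use all available neighbours,
and single-member classes fall back to replication with a warning). The
default target equalizes every class to the majority count. Balancing is a
training-set-only operation: datasets whose split role is validation or
test refuse it, and evaluation refuses balanced data. Both refusals are
enforced in code, not convention.

## Training

Adam (initial learning rate 1e-3, weight decay 1e-4), cosine annealing
`η(e) = η_min + ½(η_0 − η_min)(1 + cos(πe/T_max))` with `T_max = 100` and
`η_min = 1e-6`, batch size 256, and per-batch gradient clipping at global
L2 norm 1.0. The loss is unweighted cross-entropy (imbalance is handled by
SMOTE, not by loss weighting). Early stopping monitors validation loss
with patience 10; decreases smaller than `early_stop_min_delta` (default
1e-4, below which cross-entropy changes are numerical noise rather than
generalization gains) do not count as improvement, and the
best-validation checkpoint is restored. The test
share is held out first (default 20%), then the remainder splits 80/20
into training and validation, stratified per class. The split unit is the
beat; an inter-patient split is deliberately out of scope, and beat-level
splitting is known to give optimistic estimates on real recordings.

One master seed drives everything downstream — split, SMOTE, weight
initialization, batch shuffling, dropout — so a run is reproducible from
its manifest.

### Numerical implementation

No deep-learning framework exists in this package's dependency set, so the
network's forward and backward passes are written out analytically, layer
by layer, in a single-precision C++ engine (RcppArmadillo; all dense
algebra is BLAS `sgemm`). Single precision is the standard arithmetic for
neural-network training; dropout masks come from a dedicated
xorshift128+ stream seeded per batch. Every building block is mirrored by
a pure-R double-precision reference implementation which is the exported
API for inspection (`attention()`, `residual_block_forward()`,
`gated_fusion()`, ...); the test suite checks (a) forward parity between
the two paths to single-precision tolerance and (b) engine gradients
against finite differences of the engine loss. Weights are initialized
with fan-in-scaled Gaussians; batch-norm running statistics use momentum
0.1; the gate MLP's hidden activation is ReLU and the encoder FFN
activation is ReLU (both unconstrained by the architecture definition, so
fixed here as the common defaults).

## Synthetic data

The generator exists so that every stage — WFDB IO, preprocessing,
balancing, training, evaluation — is testable without downloading
clinical data. A beat is a sum of Gaussian deflections (P, Q, R, S, T
bumps with per-class amplitudes, centres and widths); class signatures
mirror the clinical contrasts: V widens the QRS threefold, drops the P
wave and inverts T; S attenuates P to 40% and shortens the preceding RR
interval; F is the pointwise average of the N and V templates; Q mimics a
paced/unclassifiable beat (sharp pacing spike, very wide low-amplitude
QRS, flat T) plus heavy-tailed (t, 3 df) distortion. Purely additive
noise on the N template cannot represent Q: under nearest-neighbour
geometry a noised copy of a template always lies closer to the clean
template than to another independently noised copy, so "N + noise" beats
are systematically absorbed into N; Q therefore carries its own
morphology, as real paced beats do. Records place beats at per-class RR
intervals and inject sinusoidal baseline wander plus Gaussian
high-frequency noise, annotated with MIT-BIH symbols at the R samples.
Dataset windows also render the neighbouring beats, so timing structure
(not just morphology) separates classes, as in real segmented ECG.

What this emulates — and what it does not: the synthetic classes are
separable by construction (a 1-nearest-neighbour classifier reaches ≥0.9
accuracy), morphologies are stationary within a class, and noise is
stylized. Real recordings have patient-specific morphology drift,
electrode artifacts, rhythm context spanning many beats, and genuinely
ambiguous beats. A model that learns the synthetic task therefore
demonstrates that the architecture, gradients, optimization and pipeline
wiring are correct — not that clinical-grade accuracy transfers to
MIT-BIH. Reproducing the published MIT-BIH numbers requires downloading
the database and a full-length training run (see the README's
"Reproducing" section for the optional workflow).

## Problem sizes used in the checks

The learnability check trains the full variant on 200 beats/class
(validation and test 50/class, seed fixed, at most 30 epochs) — chosen as
the smallest dataset on which the four variants train stably and the full
model reliably exceeds 0.95 macro-F1. Unit tests use 10-60 beats/class.
The ablation harness in the test suite runs 2 epochs per variant purely as
a wiring check; meaningful variant comparisons need the full protocol via
`run_ablation()` with default epochs.

## Known limitations

* Beat-level (intra-patient) splitting inflates metrics relative to
  inter-patient protocols; the package states this rather than hiding it.
* R-peak positions are taken from annotations; there is no R-peak
  detector.
* Single-lead only (lead II preferred, with a recorded fallback); no
  multi-lead fusion.
* The WFDB layer covers the MIT-BIH subset of the format family
  (header + signal formats 212/16 + MIT-format annotations), not every
  dialect.
* Training runs on one CPU; the engine is sized for the beat-window task,
  not for large-scale GPU workloads.
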