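---
title: "Methods: fused deep features with osprey-tuned autoencoder classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused deep features with osprey-tuned autoencoder classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbiclass)
```

## The problem and the model

Narrow-band laryngoscopy produces tissue patches in which vascular
patterns discriminate early laryngeal cancer from healthy mucosa. The
reference setting is a balanced four-class problem — hypertrophic blood
vessels (`Hbv`), healthy tissue (`He`), IPCL-like vessels (`IPCL`),
leukoplakia (`Le`) — over 1,320 patches of 100×100 px (330 per class).
`nbiclass` implements the full classification pipeline at desk scale:
median filtering, three fused convolutional feature extractors, an
autoencoder latent classifier, and the Osprey Optimisation Algorithm
(OOA) for hyperparameter selection.

Because the clinical patches cannot be redistributed, the package ships
a synthetic generator that reproduces the dataset's *structure* (four
balanced classes, 100×100 px RGB, optional salt-and-pepper corruption)
with four procedural texture families chosen to be separable in simple
pixel statistics. What passing tests show is therefore pipeline
correctness — learning above chance, deterministic reproduction,
contract conformance — not histological realism; no claim about
diagnostic utility on real tissue follows from them.

## Synthetic data generator

Each class is a parametric texture: `Hbv` thin curvilinear ridges
(a thresholded smooth random field) on a reddish base, `He` a smooth
low-amplitude field on a pale base, `IPCL` Gaussian puncta on a mid
base, `Le` thresholded bright plaques on a dull base. Amplitude and
frequency scalars are exposed per class (`texture_params`). Pixel values
are clamped to `[1, 254]` before corruption so injected salt (255) and
pepper (0) pixels are always identifiable; corruption replaces a
configurable fraction of pixels (default 5%, all three channels jointly)
so the median-filter stage has an observable effect. Defaults mirror the
study composition: `patch_side = 100`, `per_class_count = 330`.

The train/val/test split is stratified 70/15/15 at a fixed seed. The
reference study does not state its partitioning protocol, nor whether
patches from one patient can straddle splits; the generator has no
patient structure, so this choice is neutral here, but results on real
data would need a patient-grouped split.

Features deliberately *not* emulated: narrow-band optics, stain or
illumination variation, patient-level correlation, class imbalance,
annotation noise.

## Median filtering

Marginal (per-channel) median over a `kernel_side × kernel_side`
window, default 3 — an odd kernel makes the median an order statistic of
the window, so output values are always drawn from the input's value
set and edges survive. Borders are mirror-reflected by default
(`"edge"` replication available). The 3×3 path uses a fixed 19-exchange
vectorised minimum/maximum network; larger odd kernels fall back to a
generic sort. Filtering runs at the native 100-px resolution *before*
the extractor-side resize to 64 px, so noise suppression acts on the
pixels the noise model corrupted rather than on interpolated values.

## Feature extractors

All three extractors consume 64×64×3 inputs (bilinear resize, values
scaled to roughly [-0.5, 0.5]) and are trained on the task with
temporary softmax heads (Adam, categorical cross-entropy), then frozen.
The heads are sized to the four classes and discarded after training.

**AlexNet-style.** Five 3×3 convolutions of 96/256/384/384/256 filters
with ReLU; 2×2 stride-2 max-pooling after conv1, conv2 and conv5; conv2
uses 'same' padding with 256 filters; FC6 and FC7 have 4096 ReLU units,
each followed by dropout 0.5; the embedding is FC7 (4096-d). One
deliberate geometry choice: conv1 uses stride 2, so the flattened input
to FC6 is 4×4×256 = 4096. A stride-1 conv1 would leave 8×8×256 = 16,384
inputs and a 16,384×4096 weight matrix whose Adam state alone costs
~2 GB; stride 2 keeps the layer constants of the reference architecture
while making single-CPU training practical. Channel counts scale with a
`width` multiplier for desk-scale experiments (conv2's 256 filters are
kept exact at `width = 1`).

**SqueezeNet-style.** A stride-2 stem convolution, three fire modules
(squeeze 1×1 → parallel expand 1×1 and 3×3, concatenated; 16/64 and
32/128 squeeze/expand channels), max-pooling, dropout, a final 1×1
convolution (default 128 channels) and global average pooling; the
embedding is the pooled vector.

**Capsule network.** A convolutional stem feeds a linear stride-2
convolution whose activation map is reshaped into 8-d primary capsules
and squashed. A routed layer maps them to 8 output capsules of 16
dimensions (embedding 128-d). Routing-by-agreement runs 3 iterations:
couplings are a softmax over parents of logits started at zero,
aggregated inputs are squashed, and logits grow by the scalar agreement
between prediction and output. The squashing function bounds every
output norm strictly below 1 and is monotone in the input norm, so
capsule lengths behave as feature-presence probabilities. The number of
primary capsules is resolution-driven (8×8×32 map / 8 = 256 at default
size); counts and dimensions are configurable.

During backpropagation the coupling coefficients are treated as
constants (the widely used simplification of unrolled routing); all
other layers have exact analytic gradients, verified against central
differences at ~1e-9 relative error in the test suite.

**Fusion.** The three embeddings are concatenated in fixed order
(alexnet, squeezenet, capsnet → 4096 + 128 + 128 = 4352-d at defaults),
with span offsets recorded. Concatenation is the simplest operator
consistent with combining complementary representations; no weighting
is attempted because the downstream autoencoder learns its own mixing.

## Autoencoder classifier

Features are standardized per dimension (mean/SD of the training
split — stored in the model and re-applied at prediction). The
autoencoder is a single affine encoder and decoder with a pointwise
nonlinearity: `Z = act(We X + be)`, `Xhat = act(Wd Z + bd)`, trained
with Adam on the mean squared reconstruction error. The encoder default
is ReLU; the decoder output default is *linear*, because a ReLU (or
sigmoid) output cannot reach the negative half of standardized feature
space — with a ReLU decoder the reconstruction loss is floored far above
zero regardless of training. Both activations remain configurable
(`relu`, `sigmoid`, `linear`).

Classification is a softmax head on the latent code, fine-tuned jointly
with the encoder by cross-entropy after reconstruction pretraining, with
inverted dropout on the latent code. Two phases use the same epoch
budget. The tunable hyperparameters — latent width, learning rate,
batch size, latent dropout, epochs — form the OOA search space.

## Osprey Optimisation Algorithm

A bounded continuous minimizer (maximization by negation). Per
iteration `t` and member `i`:

1. *Exploration.* The fish set is every member with strictly lower
   fitness, plus the incumbent best. A fish `F` is chosen uniformly;
   the candidate is `x + r (F − I x)` with `r ~ U[0,1]` per dimension
   and intensity `I` drawn from {1, 2} (a `U[1,2]` variant is selectable;
   the integer form is the canonical algorithm). Candidates are clipped
   to `[LB, UB]` and accepted only on strict improvement.
2. *Exploitation.* Candidate `x + (LB + r (UB − LB)) / t`, clipped,
   greedily accepted. The divisor is the iteration counter, giving a
   decaying local step; the update direction is random, so early
   iterations explore the bound range while late ones refine.

Greedy acceptance makes every member's fitness non-increasing, hence the
best-so-far trace is monotone. The uniform stream is injectable
(`rand_fn`), which the tests use to replay a scripted iteration against
an independent trace at 1e-12.

For hyperparameter tuning, positions decode to `ae_hyperparams`
(integer dimensions rounded at decode time; the search itself stays
continuous), the objective trains the classifier on the training split
and scores macro precision `TP/(TP+FP)` on validation. Precision is
implemented as written, with a documented `fitness = "accuracy"`
switch, since the label attached to this criterion and its formula
disagree in the reference description. Failed candidates score 0 and
the search continues. Candidate seeds derive deterministically from the
master seed and an evaluation counter, so tuning is reproducible.

## Metrics

Per class in the one-vs-rest reduction: accuracy `(TP+TN)/n`, precision,
recall, F1, and AUC computed from the posterior ranking
(Mann–Whitney form; cross-checked against `pROC` in tests). Macro
values are unweighted means over classes; per-class "accuracy" is
one-vs-rest accuracy, which is why its macro can exceed macro recall on
imbalanced predictions. A class absent from the truth has undefined
AUC: reported `NA`, excluded from the macro, with a warning. Undefined
precision (no positive predictions) is scored 0 rather than dropped, a
conservative convention.

## Numerical and reproducibility choices

- All randomness flows from per-stage seeds derived from one master
  seed (`derive_seed`); identical configuration + seed gives identical
  artifacts byte-for-byte (asserted in tests).
- Weight initialization is He-scaled Gaussian; Adam uses the standard
  (0.9, 0.999, 1e-8) moments.
- `squash` guards the zero vector (maps to zero, zero gradient);
  softmaxes are max-shifted; cross-entropy clamps probabilities at
  1e-12.
- Median-of-9 uses a fixed exchange network, so no tie rule is needed
  (odd window, exact order statistic).
- Degenerate inputs (even kernels, kernels larger than the image,
  unknown labels, shape mismatches, non-finite objectives, untrained
  models) raise classed errors (`nbi_*`), tested per contract.

## Problem sizes used in the shipped checks

The package's own verification runs at deliberately small scales,
chosen as the smallest sizes at which each property is meaningful: the
dataset-composition check generates the full default 1,320 patches; the
end-to-end check uses 12 patches per class with the full-size
architecture, 1 extractor epoch and a 2×2 OOA budget (~1.5 min per
repetition); unit fixtures use micro networks (width 0.15, 32–64 px).
The OOA sphere benchmark runs n = 20, T = 100 in five dimensions. These
sizes are statements about test design, and the generator's defaults —
not the test scales — define the emulated study conditions.

## Known limitations

- Procedural textures are far easier than histology; absolute metric
  values at desk scale say nothing about clinical performance.
- Extractor training from scratch at these sample sizes is
  feature-shaping rather than representation learning; transfer from
  pretrained weights is accepted via configuration but not shipped.
- The routing backward pass is the detached-coupling approximation.
- Single-hidden-layer encoder/decoder as specified; deeper variants are
  out of scope.
- OOA population size and iteration budget for the reference results
  are not stated in the source description; defaults here (n = 6,
  T = 5 for tuning) are desk-scale choices.
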