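---
title: "Learning paradigms for wearable-sensor activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning paradigms for wearable-sensor activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(harspectrum)
```

## The problem

Human activity recognition (HAR) from body-worn inertial sensors is, in
its fully supervised form, a solved-enough classification problem — the
bottleneck is labels.  Annotating hours of multichannel accelerometer
streams is expensive, so the interesting question is how much
recognition performance survives as the supervision signal is weakened:
from full labels, through pairwise "same activity or not" constraints,
to no labels at all.  `harspectrum` implements six points on that
spectrum as one tested library:

| paradigm       | model                          | objective | input |
|----------------|--------------------------------|-----------|-------|
| supervised     | residual TCN + softmax         | cross-entropy | raw windows |
| unsupervised   | residual autoencoder           | reconstruction | features |
| weak, single   | Siamese TCN, one head          | pairwise contrastive | raw windows |
| weak, multi    | Siamese TCN, two heads         | weighted two-task contrastive | raw windows |
| self-supervised| residual autoencoder           | reconstruction + consistencies | features |
| weakly self-sup| two-stage autoencoder + Siamese| stage 1 consistencies, stage 2 + contrastive | features |

"Features" are the seven per-channel window statistics (mean, variance
— population form, 1/W — standard deviation, median, max, min,
interquartile range with linear-interpolation quartiles), giving a
`7 * C` vector per window.

## Objectives

All objectives are exported as pure functions with analytic gradients
(verified against central differences in the test suite).

* **Reconstruction** `phi_ae = (1/N) sum_i ||x_i - g(f(x_i))||^2`.
* **Contrastive** on a pair `(x_a, x_b, y)` with Euclidean embedding
  distance `D`: `y * D^2/2 + (1 - y) * max(0, delta - D)^2/2`.  Only
  dissimilar pairs closer than the margin `delta` contribute, which
  focuses learning on hard negatives.  The defined batch quantity is the
  *sum* over pairs; trainers use the mean for learning-rate stability.
* **Multi-task** `alpha * phi_act + beta * phi_pers`, one contrastive
  term per head.
* **Temporal consistency** `phi_tc(x_t) = (1/|P|) sum_{p in P_t}
  ||x_p - x_recon_t||^2` with `P_t = {t-2..t+2}` clipped at stream
  boundaries and never crossing persons.  The *inputs* of the neighbors
  are the targets; reconstructing toward neighbor reconstructions would
  admit a collapsed solution.
* **Feature consistency** `phi_fc`, same form over the k = 5 nearest
  neighbors in (z-scored) feature space, searched across the whole
  training set so that cross-person regularities can be exploited; the
  query point itself is excluded.
* **Joint self-supervised** `(1 - alpha - beta) phi_ae + alpha phi_tc +
  beta phi_fc`, and its two-branch weakly supervised extension with an
  additional `gamma`-weighted contrastive term on the encoder
  embeddings.

The weighting constants — `alpha`, `beta`, `gamma`, `delta` — have no
canonical published values, so the package's defaults are its own:
`alpha = beta = 0.3` for the self-supervised objective,
`alpha = beta = 0.1, gamma = 0.6` for stage 2 (the similarity term is
meant to dominate, with the remaining terms acting as regularizers),
and `delta = 1` for generic use.  The synthetic-scale experiment
harness uses `delta = 2` for the Siamese TCN trainers: embeddings are
not normalized there and a unit margin stops separating negatives well
before the classes are k-means-separable.  All are configurable.

## Architectures and the gradient engine

No deep-learning framework is assumed: the package carries a compact
reverse-mode gradient engine (dense, dilated *causal* 1-D convolution,
batch normalization, temporal and global max-pooling, residual blocks,
Adam and plain SGD) built on base R matrix operations.  Temporal data
travels as `(N, W, C)` arrays; convolutions are evaluated as one matrix
product per kernel tap, so batched training runs at BLAS speed.

The TCN encoder stacks residual blocks of two (conv → BN → ReLU)
stages with dilation doubling per block, identity skips when channel
counts match and pointwise linear projections otherwise, a temporal
max-pool after every second block, global max-pooling, and a linear map
to the embedding.  Default widths (4 blocks of 32/32/64/64, kernel 5,
H = 32) are the package's own, sized for CPU training.  The residual
autoencoder uses fully connected residual blocks of decreasing width
for the encoder and a plain widening stack for the decoder.

Siamese training passes both branches of each pair through the network
as one concatenated batch, so batch-norm statistics mix the branches
and weight sharing is by construction (there is only one parameter
set).  The multi-task variant adds a second linear head on the shared
trunk; with `beta = 0` and identical pairs it reproduces the
single-task trainer's trajectory exactly, which the tests assert.

The two-stage weakly self-supervised trainer strips activity labels
before stage 1, re-initializes the optimizer between stages (the
alternative — carrying Adam moments across the objective switch — is
defensible but makes the stages less independent), and draws stage-2
pairs only from a stratified label budget: per class,
`ceil(fraction * n)` windows with a minimum of one.

## The synthetic generator

The generator exists so that every loss, trainer and evaluation can be
exercised without external downloads, and so that the structural
assumptions of the consistency losses hold *by construction*:

* each activity class is a temporally stationary signature — a
  two-harmonic sinusoid with class-specific base frequency, amplitude
  (`1 + 0.3 a`), channel-mixing pattern and harmonic weight;
* each person modulates it with nuisance gain (global intensity and
  per-channel, at half the nuisance scale each), per-channel offset
  (half scale) and a phase shift — drawn from bounded uniform
  distributions with unit variance so a single extreme person cannot
  degenerate the class geometry of a 4-person draw;
* activities arrive in contiguous bouts (default 45 s, four per
  person, shuffled class permutations so every class occurs for every
  person), giving genuine temporal continuity with few boundary
  windows;
* i.i.d. Gaussian noise (default `sigma = 0.8`) on top.

The defaults put the feature space in a *boundary-error* regime: class
centroids are well separated and stable, but sample noise pushes
individual windows across class boundaries.  That is the regime in
which neighborhood-consistency training has something real to do —
its targets average ~5 temporal and 5 feature-space neighbors,
denoising each window toward its class manifold — and it mirrors the
motivation for the consistency objectives.  What the generator does
*not* emulate: activity transitions inside windows (mixed-label windows
are dropped), sensor displacement, heart-rate-like slow channels,
non-stationary activity execution.  Passing orderings on this set show
that the implementations behave as designed, not that the paradigms
would rank identically on any real dataset.

Windowing follows the field's conventions: `W = round(rate * seconds)`
samples, trailing partial windows discarded, windows spanning an
activity or person change dropped (the alternative, majority labeling,
would contaminate constraint generation), ordinals reassigned after
dropping.  Downsampling is plain decimation (keep every factor-th
sample); an anti-alias filter is deliberately not applied, to keep the
operation exactly reproducible and label-aligned.

## Evaluation

All label-free paradigms are scored by k-means (k = number of activity
classes, 10 restarts, best inertia) on the learned embeddings, followed
by the standard clustering-accuracy convention: the injective
cluster-to-class mapping that maximizes the matched count, found by a
Hungarian assignment on the contingency matrix (the package carries its
own O(n^3) solver, tested against factorial enumeration).  Macro-F1 is
computed on the mapped predictions; clusters left unmapped (k > M)
count as errors.  The supervised paradigm reports classification
accuracy.  Evaluation is record-wise on the training windows — the
synthetic harness measures representation quality, not generalization
to held-out subjects.

## Problem sizes and numerical choices

The experiment harness (`run_experiment()`, `run_ablation()`) runs at a
deliberate desk scale: ~700 windows (3 activities, 4 persons, 2-s
windows at 25 Hz with 1-s steps), a compact TCN (2 blocks, 16/32
channels, H = 16), feature networks with H = 8, Adam at `3e-3`, 300
epochs for feature-space trainers, 20 epochs and `2N` pairs for the
Siamese TCN trainers.  The learning rate and epoch counts were chosen
for convergence: at common smaller rates the autoencoders underfit
badly (reconstruction loss several times the converged value), which
distorts every downstream comparison.  Neighbor means for the
consistency losses are precomputed once per training run (the
neighborhoods and inputs are fixed), which makes the consistency
trainers nearly as cheap as the plain autoencoder.

Degenerate inputs are handled explicitly: streams shorter than one
window yield empty (not failing) window sets; constant channels yield
zero variance/IQR features; single-class data refuses to sample
dissimilar pairs; an empty stage-2 constraint set falls back to the
stage-1 model with a warning; kNN refuses `k >= N` with advice to lower
`k`.  Ties break deterministically everywhere (stable `order()` in kNN,
first-index ties in pooling and argmax).

## Known limitations

* The engine is CPU-only and sized for hundreds-to-thousands of
  windows; it is not a general-purpose deep-learning framework.
* Clustering-based evaluation has intrinsic partition variance; the
  harness reports means over seeds, and single-seed differences smaller
  than a few percent should not be over-read.
* The generator's person nuisance is affine (gain/offset/phase); real
  inter-person variation also changes waveform shape, which is why
  feature-space kNN bridges persons less on this synthetic set than on
  real feature distributions.
* Benchmark-dataset loaders (UCI-Smartphone, PAMAP2, REALDISP) are out
  of scope; the CSV reader covers generic long-format exports.
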