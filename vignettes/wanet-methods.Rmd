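---
title: "Segmenting retinal vessels with a wide-activation residual encoder-decoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting retinal vessels with a wide-activation residual encoder-decoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wanet)
```

## The problem

Retinal blood vessels are thin, branching, low-contrast structures on a
bright, vignetted circular field of view (FOV). Segmenting them pixel by
pixel is a strongly imbalanced binary classification problem: vessels
typically occupy on the order of a tenth of the FOV. `wanet` implements a
patch-based convolutional encoder-decoder for this task, together with the
whole workflow around it: preprocessing, overlapping-patch extraction and
reconstruction, training, inference, evaluation, and a synthetic retina
generator that makes the complete pipeline runnable and testable without any
external dataset.

## The model

**Wide-activation residual blocks.** A conventional residual block applies
two k x k convolutions of equal width $c_1$ and adds the input back; it
carries $2 c_1^2 k^2$ convolution weights. A wide-activation block instead
*expands* the features before the ReLU by a factor $r$ and *slims* the
identity path to width $\hat c_1$: conv$(\hat c_1 \to \hat c_2)$, ReLU,
conv$(\hat c_2 \to \hat c_1)$, with $\hat c_2 = r \hat c_1$. Requiring equal
weight counts gives $c_1^2 = \hat c_1 \hat c_2 = r \hat c_1^2$, i.e.
$c_1 = \hat c_1 \sqrt r$. With the package default $r = 4$, a slim width of
16 is equivalent in complexity to an ordinary 32-channel block while letting
four times as many features pass through the activation:

```{r}
wide_block_widths(16, r = 4)
count_params(build_wdsr_a(wide_block_widths(16), seed = 1), "conv_weights")
original_block_params(32, 3)
```

When the block input has a different channel count than the slim width, the
identity path becomes a 1 x 1 convolution; otherwise it is a pass-through,
and a block whose residual weights are all zero is exactly the identity map
(a property the test suite asserts).

**Atrous pyramid (LASPP).** At the bottleneck, four parallel 3 x 3
convolutions with dilation rates $d = 2^i$, $i = 0..3$, act on the same
input; each is followed by ReLU and the outputs are summed. A dilated kernel
sees $(k-1)(d-1)+k$ input pixels per axis, so the branches cover receptive
fields of 3, 5, 9 and 17 pixels — capillaries up to main trunks — without
extra parameters:

```{r}
sapply(c(1, 2, 4, 8), function(d) receptive_field(3, d))
```

**Weight normalization.** The pyramid convolutions are reparameterised per
output channel as $w = g\,N / \lVert N \rVert$, so the norm of the effective
kernel is the learned scalar $g$, independent of the direction $N$. Unlike
batch normalization this does not couple examples within a mini-batch. A
configuration flag (`wn_all`) extends it to every convolution.

**Assembly.** The network is built by `build_wa_net()` from a
`network_config()`: one input batch normalization (the only BN in the base
variant); three encoder wide-activation blocks of slim widths 16/32/64, each
followed by 2 x 2 max pooling; the atrous pyramid (128 channels); three
decoder stages of 2x nearest-neighbour upsampling + 3 x 3 convolution,
concatenation with the encoder skip at that resolution, and a mirrored
wide-activation block; and a head that sums a leaky ReLU (slope 0.3) on the
decoder output with a leaky ReLU on a global 1 x 1-convolution shortcut from
the post-BN input, ending in a 1 x 1 convolution to two channels with a
per-pixel softmax. Patches are 48 x 48, so three poolings bottom out at
6 x 6.

**Ablation variants.** `build_variant()` reproduces four structural
ablations: `network_1` replaces the wide blocks with pre-activated residual
blocks (BN-ReLU-conv twice) and removes weight normalization; `network_2`
additionally widens the channel sequence to 32-64-128-256-128-64-32
(read as encoder 32/64/128, bottleneck 256, mirrored decoder); `network_3`
and `network_4` use three (d = 1, 2, 4) and five (d = 1, 2, 4, 8, 16)
pyramid branches.

## The objective

Training minimises cross-entropy plus smoothed Dice loss,

$$L(\bar y, y) = L_{CE} + L_{DICE}, \qquad
L_{DICE} = 1 - \frac{2\sum_i y_i \bar y_i + k}{\sum_i y_i + \sum_i \bar y_i + k},$$

with smoothing $k = 1$, which keeps the Dice term defined when both
prediction and truth are empty. The cross-entropy treats every pixel; the
Dice term scores overlap of the rare vessel class, countering the class
imbalance. The exported `cross_entropy()` follows the summed-over-pixels
definition (a `reduction` flag switches to the mean; the sum makes the CE
term scale with patch size, and the balance between the two terms is a
genuine modelling choice, so it is exposed rather than fixed silently).

The *training loop* evaluates and differentiates the cross-entropy in logit
space (log-softmax), giving the bounded gradient $(p - y)/n$ per pixel.
This matters: with He-normal initialisation the unnormalised residual
blocks produce large logits and the softmax saturates, and the
probability-space gradient — which must clip $p$ away from 0 and 1 before
the logarithm — is exactly zero there, so optimisation would never start.
The two formulations agree wherever the softmax is unsaturated (the
gradient tests verify the analytic gradients against finite differences).

## Preprocessing and patch geometry

Each RGB image is converted to grayscale (ITU-R BT.601 weights — the common
convention in retinal pipelines), z-scored per image, min-max rescaled back
to [0, 1] (CLAHE and the gamma map need a bounded range; per-image scope is
the default because acquisition brightness varies between photographs),
enhanced with CLAHE (clip limit 2, 8 x 8 tiles — standard values, exposed in
`preprocess_config()`), and gamma-corrected with $\gamma = 1.2$.

Patches of 48 x 48 are taken either on a stride-5 sliding grid
(deterministic, row-major, with one extra edge-aligned window per axis when
the stride does not tile exactly, so that reconstruction covers every pixel)
or at seeded uniform random positions for training, optionally restricted to
patch centres inside the FOV. `reconstruct_map()` averages all overlapping
patch predictions per pixel; on the grid the extract-reconstruct round trip
is exact to floating tolerance, which the suite asserts for non-divisible
image sizes as well.

## Training and inference

`train_model()` runs mini-batch Adam (learning rate 0.001, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$, batch 32 by default) over a seeded
90/10 train/validation split, records per-epoch training loss, validation
loss and validation pixel accuracy, and retains the best-validation
parameters alongside the final ones. He-normal initialisation draws kernel
entries from $N(0, 2/\mathrm{fan_{in}})$; weight-normalisation scales start
at the column norms of the drawn directions, so the effective weights
initially equal the draws. The single input BN uses momentum 0.99 running
statistics at inference. `predict_image()` composes grid extraction, the
forward pass and overlap averaging; the default test-time stride of 5 can be
raised to trade smoothness for speed.

## The synthetic retina generator

`generate_vessel_mask()` grows seeded recursive bifurcating trees: each
branch is a straight stroke, children leave at half the opening angle
(default 40 degrees) with Gaussian angular jitter, segment lengths shrink by
a factor 0.75 per level with uniform jitter, and stroke width tapers
linearly from 4 px at the root to 1 px at the deepest level.
`render_fundus()` places the vessels dark (contrast fraction 0.35) on a
vignetted bright disc (base 0.65, vignette 0.35), blurs with a 0.7 px
Gaussian for soft edges, and adds seeded Gaussian noise (sd 0.03). With the
default 128 x 128 geometry this yields an FOV vessel fraction of roughly
10-20%, reproducing the class imbalance that motivates the Dice term.

What the generator does *not* emulate: the red-channel spectral structure of
real fundus photographs, the optic disc and macula, pathology (lesions,
exudates, haemorrhages), calibre-dependent centre-line reflexes, and
tortuosity. Passing the synthetic end-to-end test therefore demonstrates
that the architecture, losses, optimisation and plumbing work — it is not
evidence of clinical-grade accuracy on real retinas, for which the same CLI
and functions can be pointed at DRIVE/STARE-style data.

## Numerical choices

* The 3 x 3 convolutions (and their input/weight gradients) run in
  hand-written compiled kernels that compute in single precision — the
  standard precision for CNN training — with an AVX2/FMA micro-kernel
  selected at run time and a portable fallback; everything else is double.
  Consequences: forward outputs are reproducible bit-for-bit on a given
  machine, and adjoint identities hold to ~1e-5 relative rather than 1e-12.
* Probabilities are clipped at 1e-7 before logarithms in the exported loss
  functions; the trainer's log-softmax path needs no clipping.
* Zero-denominator metric ratios (e.g. specificity with no negatives) are
  reported as 0 and flagged in the report's `undefined` field.
* ROC points are generated once per block of tied scores, which makes the
  trapezoidal AUC equal the Mann-Whitney all-pairs statistic with the
  half-credit tie convention, exactly.
* Binarization threshold 0.5 by default; metrics are computed over all
  pixels unless an FOV mask is supplied (both choices surface in the
  report).

## Problem sizes used by the test suite

The test suite trains a scaled-down network (slim widths 8/16/32, pyramid
64) on 2,000 synthetic 48 x 48 patches drawn from ten 128 x 128 synthetic
retinas for 15 epochs, then evaluates held-out synthetic images at stride 5;
it also checks that performance transfers across a mild generator shift
(noise sd 0.03 to 0.045, vessel contrast 0.35 to 0.30). Unit tests use a
miniature three-level network on 16 x 16 patches. Full-scale training (the
Table-1 widths, 160k-200k patches, 100 epochs) uses the same code paths
unchanged via `network_config()` and `train_config()` defaults.

## Known limitations

* No data augmentation beyond random patch sampling, and no vessel-specific
  filtering (Gabor/Frangi) — both are deliberately out of scope.
* The training loop is single-threaded CPU code; it is sized for desk-scale
  experiments, not for reproducing benchmark-scale training runs.
* The generator's domain gap (above) means synthetic metrics should be read
  as pipeline checks, not clinical performance.
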