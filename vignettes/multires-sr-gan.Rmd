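---
title: "Multi-resolution GAN super-resolution: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution GAN super-resolution: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsr)
```

## The problem and the model

Single-image super-resolution (SR) seeks a high-resolution (HR) image $Y$
from a low-resolution (LR) observation $X$ related by a known degradation;
here, as is standard in the SR literature, $X$ is the bicubic downscaling of
$Y$ by an integer factor $r \in \{2, 4, 8\}$. In medical imaging (CT/MR
slices) the recovered high-frequency structure — lesion boundaries, fine
texture — is what matters diagnostically, which motivates an adversarial
formulation: a pure pixel-wise loss favours blurry minimisers of the
conditional mean, while a discriminator pushes the generator toward outputs
that lie on the manifold of plausible sharp images.

The package trains a generator $G_{\theta_G}$ and discriminator
$D_{\theta_D}$ in the usual min-max game

$$\min_{\theta_G}\max_{\theta_D}\;
  \mathbb{E}_Y[\log D(Y)] + \mathbb{E}_X[\log(1 - D(G(X)))],$$

with the generator minimising the weighted total loss

$$L_{\mathrm{total}} = a_1\,L_{\mathrm{MSE}} + a_2\,L_{\mathrm{adv}},
  \qquad
  L_{\mathrm{MSE}} = \frac{1}{r^2WH}\sum_{i,j}(Y_{ij}-G(X)_{ij})^2,
  \qquad
  L_{\mathrm{adv}} = -\tfrac{1}{N}\sum_n \log D(G(X_n)).$$

Defaults are $a_1 = 1$, $a_2 = 10^{-3}$ — the standard weighting for
SR-GANs, since a much larger adversarial weight destabilises training and a
much smaller one reduces the model to plain MSE regression. Both are
exposed via `loss_weights()`.

## Generator: parallel multi-resolution streams

The generator keeps **four parallel feature streams** at full, 1/2, 1/4 and
1/8 of the target resolution, with channel widths doubling as resolution
halves (32/64/128/256 by default). The LR input is first lifted to target
size by bicubic interpolation, so the top stream lives at HR size from the
stem onward; the three transposed-convolution pairs (kernel, stride) =
(5, 2), (7, 4), (11, 8) in the aggregation head then exactly undo the
internal ×2/×4/×8 drops. This pre-upsampled reading is the only one under
which the output indexing over $rW \times rH$ pixels and the stated deconvolution
kernels are mutually consistent, and it is fixed as the package's
convention (`input_mode` is not configurable).

Structure, with `generator_spec()` defaults:

* **Stem** — four bottleneck residual units (1×1 → 3×3 → 1×1, internal
  width 64, expansion 4), then a 3×3 convolution reducing 256 channels to
  the top stream's 32.
* **Stages 2–4** — each stage adds one lower stream (stride-2 3×3
  convolution from the current lowest). The stages contain 1, 4 and 3
  *exchange units*; an exchange unit runs 4 basic residual blocks (two 3×3
  convolutions each) per stream and ends with a **cross-resolution fusion**
  in which stream $k$ receives every stream $j$: identity for $j = k$,
  chained stride-2 3×3 convolutions for $j < k$, bilinear upsampling plus a
  1×1 convolution for $j > k$. Fusing at the end of every exchange unit
  (rather than once per stage) is the convention adopted where the stage
  layout is otherwise ambiguous.
* **Aggregation head** — the three lower streams are restored to full
  resolution by the transposed convolutions above, concatenated with the
  top stream (480 channels at default widths) and reduced by a single 1×1
  convolution directly to one channel, with no activation. Clipping to
  $[0,1]$ happens only at inference, never inside the loss.

Every convolution is followed by ReLU except the final prediction layer and
the last convolution of each converter/residual branch before its additive
merge. The generator contains no batch normalisation: its specification is
convolutions + ReLU only. Weights use He fan-in initialisation from a
seed recorded in the handle; the prediction layer is additionally damped
(weights ×0.1, bias 0.5) so the initial output sits near mid-grey — this
markedly shortens the early optimisation transient without changing the
model class.

Transposed-convolution geometry is solved in closed form by
`deconv_geometry()`: padding $p$ and output padding $op$ satisfy
$(s_{\mathrm{in}}-1)s - 2p + k + op = s_{\mathrm{in}} \cdot s$, giving
$p = 2, op = 1$ for all three pinned (kernel, stride) pairs. The solution is
validated at build time, so a size mismatch in the aggregation head is
impossible by construction.

## Discriminator

Eight 3×3 convolutions with channels 64→512 and stride 2 every second
layer (no pooling anywhere), batch normalisation after layers 2–8, two
dense layers (1024, then 1) and a sigmoid. Two deliberate choices:

* **Plain ReLU**, not leaky ReLU: the architecture is specified with ReLU
  throughout, and that specification wins over the more common
  leaky-ReLU discriminator convention.
* The sigmoid output is clamped to $[10^{-7}, 1-10^{-7}]$ before any
  logarithm, so both adversarial losses stay finite under perfect
  (over)confidence; clamp activations have zero gradient, which in practice
  only pauses a saturated example rather than destabilising training.

The exact stride pattern and dense width are conventions (the design is
otherwise under-determined); both are configurable in
`discriminator_spec()`.

## Degradation, augmentation, patches

The degradation operator is **bicubic with the Keys kernel** ($a = -0.5$),
antialiasing prefilter on downscale, align-corners-false sampling grid,
replicate edges, and per-output normalised weights (constants resample
exactly). This is the dominant convention in the SR literature and is
pinned so results are reproducible; `upsample_bicubic()` uses the same
kernel without the prefilter and doubles as the weakest baseline method.
Images whose sides are not divisible by $r$ are rejected rather than
cropped — silent cropping would corrupt paired evaluation.

Augmentation expands every HR image into its full 8-member dihedral orbit:
rotations by 90°/180°/270° and the horizontal flip of each, i.e. seven
additional versions per original. The orbit reading is adopted because it
is the only one consistent with "seven additional" images: rotations alone
give three, flips of all four rotations give the remaining four.

Training crops are aligned LR/HR patch pairs (`extract_patches()`): HR
origins are snapped to the LR grid so the LR patch at $(i, j)$ corresponds
exactly to the HR patch at $(ri, rj)$.

## Training schedule and numerics

Adam (moments 0.9/0.999) for both networks, initial learning rate $10^{-4}$
halved after every 50 epochs, 200 epochs — the reference schedule, exposed
in `training_config()` and verified against the closed form
`lr_at_epoch()`. Discriminator and generator alternate 1:1 per step (the
standard ratio where only "alternating" is specified), the discriminator
seeing the current SR batch detached from the generator graph. One pair in
ten (seeded) is held out for validation; the best-validation-PSNR and final
states are checkpointed. All randomness (initialisation, shuffling,
phantom content) derives from explicit seeds through one helper, so a
fixed configuration reproduces its training log bit for bit; this is
tested.

All layers, the reverse-mode tape and Adam are implemented in the package
(R with compiled im2col/GEMM kernels); every layer's analytic gradient is
tested against central differences at $10^{-6}$ tolerance, which is what
makes the training-loop results trustworthy.

## Metrics

PSNR uses peak 1 on $[0,1]$ intensities, $10\log_{10}(1/\mathrm{MSE})$,
computed on full images without border shaving; exact pairs report `Inf`
and are excluded from dataset means with a logged count (one exact pair
would otherwise dominate). SSIM is the mean over fully interior 11×11
Gaussian windows ($\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, dynamic range
1) — the original publication's constants, since no alternatives are
specified. Whether published SR tables are computed on integer or
normalised intensities is generally unstated; this package fixes the
$[0,1]$ float convention, which differs from 8-bit rounding only in the
third decimal.

## The phantom generator: what it does and does not show

`generate_phantom()` composites a constant background, a large body
ellipse with a fixed ≥ 0.3 intensity step, nested interior ellipses, small
bright/dark circular lesions, and a low-amplitude (0.06 by default)
sinusoidal texture, clipped to $[0,1]$. These choices mimic CT slices only
at the level that matters for SR mechanics — sharp boundaries, small
blobs, mild texture — and guarantee every phantom contains an intensity
discontinuity of at least 0.2, so the SR task on fixtures is never
trivial. Per-image seeds are a fixed hash of (dataset seed, index), making
datasets order-stable.

What passing tests on phantoms **does** show: the architecture is
shape-consistent, gradients reach every parameter, optimisation reduces
the intended losses, and the learned model recovers edge content that
bicubic interpolation cannot. What it does **not** show: performance on
real anatomy, robustness to acquisition noise or non-bicubic degradations,
or clinically meaningful detail recovery — the phantoms model none of
acquisition physics, and no claim beyond the mechanics transfers.

## Desk-scale experiment sizes

The test-suite and acceptance-script experiments are sized for a CPU
workstation, as the package's own reference conditions:

* *Overfit-one-phantom*: widths 8/16/32/64, stem of two width-8
  bottlenecks, one exchange unit of two blocks per stage, one 128×128
  phantom at scale 4, content loss only, 450 steps of Adam at $10^{-3}$
  (halved after 200). This reproduces the ordering "learned model beats
  bicubic" with a multi-dB margin; the raised learning rate is appropriate
  for a 450-step single-image run where the reference $10^{-4}$/200-epoch
  schedule is sized for multi-hour GPU training.
* *Discriminator separability*: bright (0.8) vs dark (0.2) noisy 32×32
  images, reduced channel widths 8–64, 200 mixed-batch steps. Real and
  fake toy images are scored in one batch so batch-norm statistics retain
  the between-class contrast; with single-class batches normalisation
  would erase exactly the signal being learned.
* *Ablation*: the aggregation head (top-stream-only vs bilinear vs
  transposed convolutions) is swapped while trunk, seed and schedule stay
  fixed; the transposed-convolution head strictly adds parameters over the
  bilinear head, which is the structural axis of that comparison.

## Known limitations

* Non-integer and anisotropic scales are unsupported; scales are pinned to
  {2, 4, 8}.
* Only grayscale 2-D images; multi-channel inputs are collapsed by channel
  mean on read.
* The degradation model is bicubic only — no blur/noise kernels, no blind
  SR.
* 16-bit output requires TIFF (the PNG writer is 8-bit).
* CPU-scale throughput: the compiled kernels are single-threaded im2col +
  BLAS; full-scale (256-wide, 200-epoch) training is out of desk reach,
  which is why the shipped experiments are property-based rather than
  benchmark reproductions.
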