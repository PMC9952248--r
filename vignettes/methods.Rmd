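---
title: "Methods: mask-guided adversarial inpainting for annotated ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mask-guided adversarial inpainting for annotated ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usginpaint)
```

## The problem

Clinical 2D ultrasound images of ovarian tumours are routinely overlaid
with clinician-drawn symbols: caliper crosses marking measurement
endpoints, dashed ellipses outlining the lesion, and letters or digits.
These marks occlude tissue and bias downstream analysis (for example,
lesion segmentation). Removing them is a free-form image-inpainting
problem with one structural twist: the pixels under a symbol have **no
ground truth** — the true speckle pattern behind an overlay is simply
unknown. Any training scheme that pretends otherwise learns to copy
artifacts.

`usginpaint` implements a mask-guided generative adversarial network
(GAN) for this task, together with a seeded synthetic phantom generator
that *does* provide exact ground truth, so every component can be tested
quantitatively end to end.

## Mask guidance

Let $m_\text{prior} \in \{0,1\}^{H\times W}$ mark the symbol pixels of an
image (the *prior mask*), and let $m_\text{gen}$ be a random irregular
brush-stroke mask. Training masks are composed as

$$ m \;=\; \operatorname{clamp}_{[0,1]}\!\big(m_\text{gen} - m_\text{prior}\big), $$

implemented by `compose_training_mask()`. Because the subtraction is
clamped at zero, $m$ can never overlap $m_\text{prior}$: the network is
only ever trained to reconstruct regions whose true content is known
(clean tissue hidden by a synthetic brush stroke), never the unknowable
pixels under a symbol. When the prior mask is empty the composition
reduces to $m = m_\text{gen}$. The training pipeline audits this
invariant on every batch and stops if it is ever violated.

At inference time the hole to fill is the symbol region itself
(`inpaint(..., mask_source = "prior")`), and the network generalises from
brush-shaped holes to symbol-shaped ones. Quantitative evaluation, by
contrast, uses freshly generated irregular masks drawn from a disjoint
seed namespace (`test_seed_offset` in `run_config()`), because only
there does a pixel-level ground truth exist.

Irregular masks are random polylines: 1–4 strokes of 4–12 vertices,
segment length 16–60 px and thickness 8–24 px at a 256×256 reference
resolution, rasterised with Bresenham lines and disc dilation, capped at
35% image area (`brush_params()`, `generate_irregular_mask()`). For
other resolutions the length/thickness parameters scale linearly with
image side.

## Architecture

The generator (`generator_forward()`) takes the corrupted image
concatenated with the mask (4 input channels), applies three stride-2
convolutional downsamplings, nine *fast Fourier convolution* (FFC)
residual blocks at the bottleneck, and three transposed-convolution
upsamplings back to 3 channels with a sigmoid output.

Each FFC unit splits channels into a *local* branch (ordinary 3×3
convolution) and a *global* branch processed by a **spectral transform**:

1. real 2-D FFT of the feature map (`rfft2`),
2. concatenation of real and imaginary parts along channels,
3. a 1×1 convolution in the frequency domain,
4. batch normalisation + ReLU,
5. inverse FFT back to the spatial domain.

A single frequency-domain pixel mixes information from the entire image,
giving every bottleneck layer a global receptive field — the property
that lets the network propagate speckle statistics across large holes.
The global branch additionally passes through a squeeze-and-excitation
(SE) channel-attention gate. Cross connections (local→global,
global→local) fuse the two branches; a residual block is two FFC units
plus an identity skip on both paths.

The discriminator is a conditional patch discriminator: it sees the mask
alongside the (real or inpainted) image and emits a logit map over
overlapping patches, plus intermediate feature maps used by the feature
loss below.

## Loss

Training minimises the weighted sum

$$ L \;=\; \eta_1 L_1 + \eta_2 L_\text{adv} + \eta_3 L_\text{HRF} +
   \eta_4 L_\text{feat}, \qquad (\eta_1,\eta_2,\eta_3,\eta_4) = (10, 10, 30, 100), $$

with `total_loss()` combining:

- `l1_loss()` — mean absolute pixel error against the known-clean target;
- `adversarial_losses()` — the non-saturating logistic GAN loss (at zero
  logits the discriminator loss is exactly $\log 4$ and the generator
  loss $\log 2$, which the tests pin down);
- `hrf_perceptual_loss()` — mean squared error between features of a
  *frozen, seeded, high-receptive-field* convolutional extractor (three
  dilated stages, widths 8/16/16). A fixed random extractor is used
  because no pretrained classifier is available in base R; a frozen
  random projection still measures structural agreement at multiple
  scales and, critically, is fully deterministic;
- `disc_feature_loss()` — L1 distance between discriminator feature maps
  of real and fake images, which stabilises adversarial training.

All four gradients are derived by hand and verified against finite
differences in the test suite.

## The numerical engine

No deep-learning runtime is assumed. The package contains a small
reverse-mode engine in base R with Rcpp kernels for the two hot gather /
scatter loops:

- tensors are `(H, W, N, C)` arrays (channels last);
- convolutions use im2col/col2im with cached integer index maps;
- transposed convolution is zero-interleaving followed by a stride-1
  convolution;
- batched 2-D FFTs are two `stats::mvfft` passes; the adjoints of
  `rfft2`/`irfft2` are derived analytically (the redundant Hermitian
  half needs a weight-2 correction) and checked by inner-product
  identities;
- batch normalisation keeps running statistics, so evaluation mode is a
  pure deterministic function of the weights — repeated calls are
  bit-identical, checkpoints resume exactly, and one weight set serves
  any input size divisible by 8 (smaller or non-divisible inputs are
  reflection-padded and cropped back);
- optimisation is Adam over parameter trees.

Determinism is end to end: every stochastic step (weight init, mask
generation, batch order, speckle) flows from an explicit seed through
an isolated RNG scope, so two runs from the same seed produce identical
loss traces and identical weights.

## The phantom

`phantom_spec()` / `phantom_triplet()` synthesise a seeded test-card:
a dark elliptical lesion (level 0.15) in a brighter field (0.60) with
multiplicative speckle (strength 0.08 — strong enough that inpainting
cannot be solved by smoothing, weak enough that structure dominates),
overlaid with yellow caliper crosses, a dashed elliptical outline and
5×7-bitmap glyphs, each dilated by 1 px. The triplet returns the clean
image, the annotated image, and the exact symbol mask — so hole-region
error against the *known clean* image is measurable, which is impossible
on real data. Geometry primitives have closed-form pixel counts (a
cross of arm $L$ covers $2(2L+1)-1$ pixels; a Bresenham segment covers
$\max(|\Delta i|, |\Delta j|)+1$) that the tests verify exactly.

## Training presets

`run_config()` holds full-scale defaults (256×256, batch 16, Adam
learning rate $10^{-4}$). `tiny_run_config()` is a desk-scale preset for
CPU experimentation: 64×64, batch 4, learning rate $2\times10^{-3}$,
generator channels (16, 32, 64, 64), and a discriminator learning-rate
factor of 0.1. The reduced discriminator rate is a standard small-GAN
stabilisation: with so few images and parameters an equally-paced
discriminator saturates (its loss collapses toward zero and the
generator's adversarial term explodes), which we observed directly at
desk scale; at 0.1 the adversarial losses settle near their equilibrium
values ($\log 4$ and $\log 2$) and reconstruction drives learning.

## Metrics

- `ssim()` — structural similarity with the standard 11×11 Gaussian
  window ($\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$); self-SSIM is
  exactly 1.
- `fid()` / `feature_stats()` — Fréchet distance between Gaussian
  feature statistics, with a symmetric-eigendecomposition matrix square
  root; in one dimension it reduces to
  $(\mu_1-\mu_2)^2 + (\sqrt{\sigma_1^2}-\sqrt{\sigma_2^2})^2$, which the
  tests check against 100 random cases.
- `lpips_distance()` — a learned-perceptual-style distance using the
  same frozen extractor as the HRF loss, with per-channel weights.
- `miou()` — mean intersection-over-union for segmentation maps, checked
  against brute-force pixel counting.

## Limitations

- The phantom is a geometric test-card, not a simulation of ultrasound
  physics; it validates the machinery, not clinical performance.
- The perceptual losses use frozen random extractors rather than a
  pretrained network, so their absolute values are not comparable with
  published LPIPS/FID numbers.
- The dashed lesion outline sits exactly on the lesion boundary. The
  precise boundary position under an outline hole is genuinely ambiguous
  from the surrounding context, so hole-region error concentrates there:
  at desk scale the model restores brush-shaped held-out holes close to
  the speckle noise floor while the outline band dominates the residual
  symbol-region error. Larger images, more data and longer schedules —
  the full-scale preset — are expected to shrink (but cannot fully
  remove) this ambiguity.
- The base-R engine is single-threaded; the full-scale preset is
  included for completeness but is impractical without substantial
  compute time.
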