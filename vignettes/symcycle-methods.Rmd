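---
title: "Unsupervised lung-tumor segmentation by symmetry-constrained cycle-consistent translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised lung-tumor segmentation by symmetry-constrained cycle-consistent translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(symcycle)
```

## The problem and the model

Supervised tumor segmentation needs voxel-level annotations, which are
expensive to produce. This package implements an unsupervised alternative:
learn, from *unpaired* pools of tumor-bearing ("unhealthy", $x$) and
tumor-free ("healthy", $y$) lung CT slices, a translation $G_{xy}$ that maps
an unhealthy slice to a synthetic healthy counterpart. Because a well-trained
$G_{xy}$ changes only the tumor, the clipped residual
$\max(x - G_{xy}(x), 0)$ is a tumor-evidence map from which a binary mask is
extracted by thresholding and morphological clean-up. No mask ever enters
training; masks are used for evaluation only.

Five networks are trained jointly:

* two U-Net generators $G_{xy}$, $G_{yx}$ (entry convolution to
  `base_channels` feature maps, `depth` stride-2 down-steps doubling the
  channels, mirrored transposed-convolution up-steps with skip
  concatenation, logistic output so values stay in $[0,1]$);
* two patch discriminators $D_x$, $D_y$ (entry convolution to
  `first_channels` maps, three stride-2 layers with instance normalization,
  single-channel score map at 1/8 resolution);
* a similarity discriminator $D_{smi}$ applied to the left half and the
  mirrored right half of a slice. Healthy lungs are nearly mirror-symmetric,
  while tumors appear in one lung, so the *scalar symmetry score*
  $s = \overline{D_{smi}(\text{left})} - \overline{D_{smi}(\text{right})}$
  should be near 0 for healthy slices and near $\pm 1$ for unhealthy ones.

The generator objective is

$$\ell_{gen} = \ell_{gan} + \lambda_c\,\ell_{cycle} + \lambda_i\,\ell_{id}
  + \lambda_s\,\ell_{sym},$$

with the least-squares adversarial term
$\ell_{gan} = \|D_y(G_{xy}(x)) - 1\|^2 + \|D_x(G_{yx}(y)) - 1\|^2$, the
cycle-consistency term
$\ell_{cycle} = \|G_{yx}(G_{xy}(x)) - x\|_1 + \|G_{xy}(G_{yx}(y)) - y\|_1$,
the identity term
$\ell_{id} = \|G_{xy}(y) - y\|_1 + \|G_{yx}(x) - x\|_1$, and a symmetry term
pushing synthetic healthy slices toward $s = 0$ and synthetic unhealthy ones
toward $|s| = 1$. The discriminators minimize the usual least-squares
real-vs-fake objective, and $D_{smi}$ minimizes
$s(y)^2 + s(y')^2 + (|s(x)|-1)^2 + (|s(x')|-1)^2$. Defaults are
$\lambda_c = 10$, $\lambda_i = 5$; setting $\lambda_s = 0$ (or
`similarity = FALSE`) recovers a plain cycle-GAN, which is the ablation
baseline.

Each training step performs three sequential updates (generators, patch
discriminators, similarity discriminator) with Adam
($\beta_1 = 0.5, \beta_2 = 0.999$). The reference schedule is 200 epochs at
learning rate $2\times 10^{-4}$, constant for 150 epochs then linearly
decayed to exactly zero — `lr_at_epoch()` implements this contract.

### Conventions that the printed formulas leave open

* **Means, not sums.** Every squared norm is the mean of squared elements
  over a score map (and batch), and every $\ell_1$ term a mean absolute
  pixel difference. This keeps the loss magnitudes independent of image and
  map size, so $\lambda_c = 10, \lambda_i = 5$ remain balanced at reduced
  resolution.
* **Scalar symmetry score.** $D_{smi}$ emits a score map (64x32 for a
  512x256 half); the map is spatially averaged before the left-right
  comparison, which makes $|s|$ a single well-defined number. An
  element-wise comparison would be the natural alternative; the scalar form
  was chosen because the optimum targets ("close to each other", "close to
  1") are stated for slice-level quantities.
* **Symmetry feedback to the generators.** Without a $\lambda_s$ term the
  similarity discriminator would never influence synthesis; the term is
  therefore part of the generator objective with a configurable weight
  (default 1), and the decomposition above holds exactly with
  $\lambda_s = 0$.
* **Generator entry stride.** The stated entry stride of 2 is incompatible
  with four symmetric down/up steps mapping 512x512 to 512x512; the entry
  layer uses stride 1 and only the four down-steps halve the resolution.
* **Down/up-sampling operators.** Stride-2 convolution down, stride-2
  transposed convolution up (output padding 1, so sizes double exactly);
  all kernels 3x3 with padding 1; leaky-ReLU slope 0.2 everywhere; batch
  normalization in the generators (running statistics kept for inference),
  instance normalization in the discriminators (none on their entry layer).

## Intensity normalization

CT values in HU are mapped to $[0,1]$ by
$f(x) = \mathrm{clip}((x + \text{offset})/1500,\, 0,\, 1)$ with offset 0 as
the literal published rule. The literal rule clips every value below 0 HU,
which erases the air/lung-parenchyma contrast: lung tissue (about -800 HU)
and air both map to exactly 0, and a 20 HU tumor sits at 0.013 of the full
scale. At the reference scale (hundreds of epochs over thousands of slices)
the adversarial signal still converges; at desk scale it does not move the
output logits far enough to matter. The `offset` parameter exists for this
reason: `hu_offset = 1000` maps air to 0, lung to about 0.13 and soft
tissue to about 0.69, preserving the contrasts that drive both synthesis
and the residual. The model object remembers its training offset and reuses
it in `predict()` and `segment_volume()`.

A related numerical choice: each generator's output bias is initialized at
the logit of the training pools' mean intensity
(`init_output_bias = TRUE`), so synthesis starts in the identity regime
instead of mid-gray. With randomly initialized biases a short schedule
spends all of its steps just drifting the output level toward the data
range.

## Segmentation chain

`segment_volume()` runs, per volume: per-slice synthesis with $G_{xy}$;
clipped residual (negative residuals are synthesis noise, since tumors are
hyperdense relative to parenchyma); Otsu thresholding over a 256-bin
histogram spanning the residual's value range — one threshold per *volume*
by default, because slice-wise thresholds on tumor-free slices hallucinate
masks from noise (`per_slice_otsu = TRUE` restores slice-wise behavior);
binary median filtering (3x3x3 majority by default, 3x3 for single
slices); and an in-plane morphological opening with the radius-1 Euclidean
disk, i.e. the 3x3 cross — the only nontrivial disk of diameter at most
2 pixels. The opening removes structures thinner than the element, which
also bounds the smallest detectable tumor at roughly two pixel spacings in
diameter. Degenerate inputs are pinned: a constant residual yields an empty
mask, and the Otsu mask is invariant under positive rescaling of the
residual. Inference uses batch statistics in the generator's batch
normalization by default (`bn_mode = "batch"`), matching the statistics
regime the network was optimized under; `"running"` averages are kept in
every checkpoint and can be selected instead.

## Evaluation metrics

Overlap is reported as Dice, PPV (precision) and SEN (recall) in percent;
boundary agreement as HD95 (max over both directions of the 95th-percentile
nearest-surface distance) and ASD (mean nearest-surface distance pooled over
both directions), in mm. Boundary voxels are mask voxels with an unset face
neighbor (4-connectivity in 2D, 6 in 3D), with coordinates scaled by the
voxel spacing, so anisotropic spacings are handled. Percentiles use linear
interpolation (R quantile type 7); the convention is pinned for
reproducibility. Empty-mask policy: two empty masks give Dice 100 with a
warning, one empty mask gives 0; surface metrics are undefined on empty
masks and such cases are excluded from surface summaries with a logged
count. The printed ASD formula could also be read as averaging the two
directed means; the pooled symmetric form was adopted as the field
standard. Cohort summaries report mean, SD, median and IQR
(25th-75th percentile).

## The phantom generator

`make_phantom_cohort()` emulates the study conditions without any private
data: a body ellipse on air background, two lung ellipses exactly mirrored
about the vertical midline, smooth symmetric parenchymal texture (cosine
modes in the mirrored coordinate), optional asymmetric jitter applied to
one randomly chosen lung (a fraction `asymmetry_jitter` of the texture
amplitude — this is what makes the symmetry discriminator's job nontrivial
without leaking the tumor label), Gaussian HU noise, and, in unhealthy
slices, a single hyperdense disk (20 HU, near soft tissue) confined to one
lung with its rasterized support as the ground-truth mask. 3D stacks sweep
a sphere through contiguous slices so per-slice disks assemble into a
consistent mask volume. Defaults: 64x64 px at 0.977x0.977 mm, 1 mm slices,
200 slices per pool, tumor radii 2-5 mm, noise 20 HU, texture 30 HU,
jitter 0.3. Everything is a pure function of the spec, including its seed.

What the phantom does *not* emulate: airway/vessel trees, respiratory
motion, scanner artifacts, inter-patient anatomical variability, and
partial-volume effects. Passing the end-to-end checks therefore shows that
the translation-residual mechanism works as designed, not that the method
reaches any particular accuracy on clinical CT.

## Reduced-scale end-to-end protocol

The reference conditions (512x512 slices, 8723/8940-slice pools, 200
epochs, five networks on GPUs) are far beyond a desk-scale CPU run, so the
end-to-end tests and `scripts/acceptance.R` use a protocol chosen once as
the package's own study size: 32x32 px slices at 1.954 mm spacing (half the
default resolution, so tumor radii are doubled to 4-10 mm to preserve their
2-5 px rasterized size), 48 training slices per pool with 12 held-out
slices per pool, base-8 generators with first-16-channel discriminators,
batch 8, 15 epochs (5 decay) at learning rate $10^{-3}$, offset-1000
normalization, seeds {1, 2, 3}, with the full model and the
$\lambda_s$-disabled cycle-GAN ablation trained under identical conditions.
The learning rate is raised above the reference $2\times 10^{-4}$ because a
120-step schedule at the reference rate cannot traverse the required logit
range (Adam's step size is bounded by the learning rate); the reference
value remains the package default for full-scale runs. Under this protocol
held-out tumor phantoms reach mean slice Dice well above 0.6, healthy
phantoms produce mask fractions below 1%, and the full model's mean Dice
is expected to be at least the ablation's, mirroring the reference
ordering directionally.

## Known limitations

* The smallest detectable tumor is set by the opening element (about two
  pixel spacings in diameter); smaller blobs are removed as noise.
* Training is 2D; inter-slice coherence enters only through the 3D median
  filter.
* The adversarial optimum is a moving target: short schedules can leave
  individual tumors partially removed, which lowers SEN before it lowers
  PPV.
* Bit-for-bit reproducibility holds for a fixed BLAS and thread
  configuration (the determinism contract of the tests); different BLAS
  builds may differ in the last ulps.
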