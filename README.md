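# symcycle

Unsupervised lung-tumor segmentation in CT by symmetry-constrained
cycle-consistent adversarial translation.

## What it does, and for whom

Supervised tumor segmentation needs voxel-level annotations. `symcycle`
implements an annotation-free alternative for researchers working with lung
CT: from *unpaired* pools of tumor-bearing slices ($x$) and tumor-free
slices ($y$) it learns a generator $G_{xy}$ that synthesizes a healthy
counterpart of a tumor-bearing slice. The clipped residual
$\max(x - G_{xy}(x), 0)$ is then a tumor-evidence map, and a binary mask is
extracted by Otsu thresholding, binary median filtering and a morphological
opening. Masks are used only for evaluation, never for training.

Five networks are trained jointly with Adam ($\beta_1=0.5, \beta_2=0.999$)
in a three-step alternating scheme:

* U-Net generators $G_{xy}, G_{yx}$ and patch discriminators $D_x, D_y$
  with the least-squares adversarial objective
  $\ell_{gan} = \|D_y(G_{xy}(x))-1\|^2 + \|D_x(G_{yx}(y))-1\|^2$,
  cycle consistency
  $\ell_{cycle} = \|G_{yx}(G_{xy}(x))-x\|_1 + \|G_{xy}(G_{yx}(y))-y\|_1$
  and identity term
  $\ell_{id} = \|G_{xy}(y)-y\|_1 + \|G_{yx}(x)-x\|_1$, combined as
  $\ell_{gen} = \ell_{gan} + \lambda_c \ell_{cycle} + \lambda_i \ell_{id}$
  with $\lambda_c = 10$, $\lambda_i = 5$;
* a bilateral-symmetry discriminator $D_{smi}$ that scores the left half
  and the mirrored right half of each slice: healthy lungs should score
  alike (scalar score $s \approx 0$), tumor-bearing ones apart
  ($|s| \approx 1$). Disabling it (`similarity = FALSE`, the `--no-similarity`
  flag) yields the plain cycle-GAN ablation baseline.

Segmentation quality is evaluated with Dice / PPV / SEN (percent) and the
surface distances HD95 and ASD (mm, spacing-aware). A seeded generator of
mirror-symmetric lung phantoms stands in for clinical data, so the whole
pipeline runs end-to-end from an empty directory.

## Worked example

```r
library(symcycle)

spec <- phantom_spec(image_size = 32, pixel_spacing = 1.954,
                     tumor_radius_range = c(4, 10),
                     n_healthy = 60, n_unhealthy = 60, n_volumes = 0,
                     seed = 101)
cohort <- make_phantom_cohort(spec)

cfg <- train_config(total_epochs = 15, decay_epochs = 5, initial_lr = 1e-3,
                    batch_size = 8, seed = 1)
fit <- symcycle(cohort$unhealthy[1:48], cohort$healthy[1:48],
                gen_spec = generator_spec(32, 8),
                disc_spec = discriminator_spec(32, 32, 16),
                config = cfg, hu_offset = 1000)
print(fit)
#> Symmetry-constrained cycle-consistent translation model
#> Call: symcycle(x = cohort$unhealthy[1:48], y = cohort$healthy[1:48], ...
#> Slices 32x32, generator base 8 channels, depth 4; with similarity discriminator
#> Trained 15 epochs (90 steps); final-epoch means: l_gen 2.853, l_dis 0.043, l_smi 0.020

# segment held-out tumor-bearing slices and score them
masks <- lapply(49:60, function(i) predict(fit, cohort$unhealthy[[i]], type = "mask"))
report <- evaluate_cohort(masks, cohort$masks[49:60], spacing = c(1.954, 1.954))
print(report)
#> Segmentation metrics over 12 cases
#>   dice_pct  mean   69.67 +/-  11.35  median   68.27  IQR 61.20-80.00
#>   ppv_pct   mean   64.97 +/-  20.25  median   59.38  IQR 52.13-75.30
#>   sen_pct   mean   83.94 +/-  16.41  median   87.24  IQR 77.78-93.61
#>   hd95_mm   mean   23.92 +/-  10.64  median   26.65  IQR 22.72-28.82
#>   asd_mm    mean    6.24 +/-   2.75  median    6.93  IQR 5.38-8.00
```

A mean Dice near 70% after only 90 training steps means the generator has
learned to remove the tumor; the high sensitivity with lower precision
(and the correspondingly large slice-wise HD95) shows the short schedule
still over-segments — single-slice inputs are thresholded per slice, so a
few distant false-positive specks survive on the hardest slices, a known
behavior of slice-wise Otsu that volume-level thresholding avoids. A
healthy slice run through the same chain yields an (almost) empty mask.
`plot(fit)` draws the loss trajectories, `residuals(fit)` the
tumor-evidence maps, and `predict(fit, x, type = "healthy")` the synthetic
healthy counterparts.

A thin command-line interface (`inst/cli/symcycle.R`) chains the same steps
from a YAML config: `phantom`, `train` (with `--no-similarity`), `segment`
(`--per-slice-otsu`, `--median 2d|3d`, `--hu-offset N`) and `evaluate`.

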