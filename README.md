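# vesselnoise

Retinal vessel segmentation is trained from manual annotations whose pixels
are not all where the vessels actually are: observers disagree on capillary
courses and on boundary pixels, so a share of every "ground truth" mask is
*positionally* wrong. `vesselnoise` is an R toolkit for measuring what that
costs. It implements a complete patch-based U-Net segmentation pipeline for
fundus photographs together with a controllable positional label-noise
injector, and experiment harnesses that quantify how segmentation quality
decays with the magnitude and prevalence of annotation error — and how much
of it label cleaning recovers.

The package is aimed at researchers studying annotation quality and
noise-robust learning in medical image segmentation, and at anyone who
needs a self-contained, dependency-light vessel segmentation baseline in R.

## The method

- **Preprocessing.** Grayscale conversion (luma or green channel), z-score
  normalization `I' = (I − μ)/σ`, min–max rescale to 8-bit, CLAHE (clip
  limit `c = 2.0`, `8 × 8` tiles), gamma adjustment
  `J = 255 (I/255)^{1/γ}` with `γ = 1.6`.
- **Balanced patch sampling.** 2200 overlapping `48 × 48` patches per
  training image, all fully inside the field of view. Patches with 1–200
  vessel pixels are *small-vessel* patches; solving
  `f·P + (1 − P) = 0.5` for the measured uniform fraction `f = 0.37`
  gives `P ≈ 0.8`: 80% of patches are drawn uniformly, 20% from the
  small-vessel pool. Patch sets are quadrupled by 90°/180°/270° rotations.
- **Model.** A lightweight U-Net (two 3×3 conv + BN + ReLU + 20% dropout
  per stage, 2×2 max pooling, nearest-neighbor upsampling, skip
  concatenation) with *dynamic attention*: scaled dot-product attention
  `S = QKᵀ/√d_k` between the pooled decoder state and the spatial
  positions of a feature map, whose projected context is broadcast-added
  to the map. Trained with pixel-wise cross-entropy on one-hot labels
  (SGD, 20 epochs, batch 32, lr 0.1, momentum 0.9).
- **Positional label noise.** A radial deformation on each label patch:
  pixels at radius `r ≤ R = 24` from the patch center are resampled from
  `r' = R (r/R)^β` along their ray; `β = 1 + λ` maps the noise level λ to
  the deformation strength, and a noise ratio ρ controls which fraction of
  patches is deformed. Baseline image corruptions (Gaussian noise,
  low-resolution, uniform blur, fovea blur) support a noise-type ablation.
- **Evaluation.** Stride-10 overlapping tiling, prediction averaging,
  thresholding at 0.5, and FOV-restricted Acc / Sp / Sn / Precision / F1 /
  AUC.

A seeded synthetic fundus generator (circular FOV, uneven illumination,
branching vessel trees with 1–8 px widths, exact rasterized ground truth)
makes every stage runnable with no external data.

## Worked example

```r
library(vesselnoise)

# a small synthetic dataset: 4 training and 2 test images
data <- generate_dataset(synth_config(seed = 11), n_train = 4, n_test = 2)

cfg <- experiment_config(
  sampling = sampling_config(patches_per_image = 200),
  model    = model_config(depth = 2, base_channels = 4,
                          attention = "bottleneck"),
  train    = train_config(epochs = 10),
  augment  = FALSE, seed = 101)

# clean baseline vs strongest positional label noise
tbl <- sweep_noise_level(data, lambda_list = c(0, 0.8), cfg)
summarize_sweep(tbl)
```

```
  lambda rho corruption       acc        sp        sn precision        f1       auc
1    0.0   0  nonlinear 0.9353809 0.9302619 0.9971855 0.5455034 0.7039070 0.9891897
2    0.8   1  nonlinear 0.8966039 0.9075881 0.7685695 0.4104345 0.5335986 0.9320275
```

Deforming every training label at level λ = 0.8 (i.e. `β = 1.8`) costs this
run about 23 points of sensitivity and 17 points of F1 on clean test
images, while specificity barely moves — the model stops finding vessels
rather than hallucinating them, which is the failure mode expected when
positional noise dominates the supervision.

The same harness exposes ratio sweeps (`sweep_noise_ratio`), the noise-type
ablation (`sweep_noise_type`), and the cleaning comparison
(`cleaning_comparison`), plus `plot_sweep()` for quick figures. A thin CLI
(`exec/vesselnoise`) wraps the same functions:

```sh
vesselnoise synth --n-train 20 --n-test 20 --seed 1 --out-dir data/
vesselnoise sweep --mode level --manifest data/manifest.csv --seed 1 --out-dir results/
```

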