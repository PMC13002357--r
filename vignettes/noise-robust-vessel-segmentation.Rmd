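---
title: "Quantifying positional label noise in retinal vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying positional label noise in retinal vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselnoise)
```

## The problem

Manual vessel annotations in fundus photographs are imperfect: observers
disagree most on capillaries and on boundary pixels, so a sizeable share of
"ground truth" pixels are positionally wrong rather than categorically
wrong. `vesselnoise` implements a complete patch-based segmentation pipeline
together with a controllable *positional* label-noise injector, so that the
sensitivity of a U-Net segmenter to annotation errors can be measured
systematically: how do sensitivity (Sn), specificity (Sp), F1 and AUC decay
as the magnitude (noise level $\lambda$) and prevalence (noise ratio
$\rho$) of label deformation grow, and how much does removing the corrupted
labels recover?

## Pipeline and model

**Preprocessing.** Color fundus images are converted to one grayscale
channel (ITU-R 601 luma by default; a green-channel mode is available since
vessel contrast concentrates there), z-score normalized over all pixels
$I' = (I - \mu)/\sigma$ (population SD), min--max rescaled to 8-bit, passed
through CLAHE, and gamma-adjusted with $J = 255\,(I/255)^{1/\gamma}$.
Defaults are $\gamma = 1.6$ and CLAHE with clip limit $c = 2.0$ on an
$8\times 8$ tile grid. The 8-bit rescale between normalization and CLAHE is
a bridge forced by CLAHE's histogram domain; it is monotone, so it changes
no orderings. Our CLAHE caps each 256-bin tile histogram at $c$ times the
average bin height, redistributes the excess uniformly over all bins in one
pass, and blends tile mappings bilinearly between tile centers. Degenerate
constant rasters raise an error rather than silently returning zeros.
Rounding everywhere uses round-half-away-from-zero for cross-platform
bit-stability. Preprocessing statistics are computed over the full frame;
an FOV-restricted variant was considered but the full frame is the default
because the dark surround is constant and stable across samples.

**Patch sampling.** Training uses $48\times 48$ patches fully inside the
field of view, 2200 per image, sampled with replacement. Patches whose
label windows hold 1--200 vessel pixels are "small-vessel" patches; with a
measured uniform-sampling fraction $f$ of such patches, drawing a share
$P$ uniformly and $1-P$ from the small-vessel pool yields a mixed fraction
$fP + (1-P)$. Solving $0.37\,P + (1-P) = 0.5$ gives $P \approx 0.794$,
used as $P = 0.8$: an oversampling rule that roughly balances thin vessels
against trunks. We require at least one vessel pixel for the dedicated
pool (an empty window contains nothing to oversample); `include_empty`
restores the literal 0--200 reading. Patch sets are quadrupled by exact
90/180/270-degree rotations. At test time the image is tiled with stride
10 (zero-padded bottom/right), every patch is predicted, and overlapping
predictions are averaged; stride 48 reproduces the degraded "seamless"
tiling arm.

**Positional label noise.** For a patch with center $c$ and radius
$R = s/2 = 24$, each pixel at radius $r \le R$ is resampled from radius
$r' = R\,(r/R)^\beta$ along its ray ($p' = c + \frac{r'}{r+\varepsilon}(p-c)$,
$\varepsilon = 10^{-8}$); pixels beyond $R$ are untouched. $\beta > 1$
zooms the center in, $\beta < 1$ out, $\beta = 1$ is the identity. The
noise level is mapped as $\beta = 1 + \lambda$ (zoom-in default), with
zoom-out ($\beta = 1/(1+\lambda)$) and per-patch random direction
available — only the displacement magnitude, not its direction, matters
for the sensitivity question. Labels are resampled with nearest-neighbor
lookup so they stay binary without a second thresholding rule; a bilinear
variant would require one. The deformation is applied per patch, and a
noise ratio $\rho$ deforms a seeded uniform subset of exactly
$\mathrm{round}(\rho N)$ patches, with flags recording the selection so the
cleaning arm can drop precisely those patches. Baseline image-level
corruptions (additive Gaussian noise, down/up-sampling, uniform box blur,
fovea-restricted blur) implement the noise-type ablation; their strength
scales (noise SD $25\lambda$, resampling factor $1+3\lambda$, kernel width
$1 + 2\,\mathrm{round}(4\lambda)$) are package conventions chosen to span
mild-to-severe degradation, since only the kinds, not the scales, are part
of the design.

**Model.** A lightweight U-Net on $48\times 48$ inputs: `depth` encoder
stages of two $3\times 3$ same-padded convolutions with batch
normalization, ReLU and 20% dropout, $2\times 2$ max pooling between
stages, channel width doubling per stage; a symmetric decoder with
$2\times 2$ nearest-neighbor upsampling (parameter-free, followed by the
channel-halving convolution), skip concatenation, and a final $1\times 1$
two-channel softmax head. *Dynamic attention* refines feature maps with
scaled dot-product attention: the spatial positions of a feature map form
the key/value sequence $H$, the aligned decoder map is pooled into a query
state $d$, scores $S = QK^\top/\sqrt{d_k}$ are normalized row-wise by
softmax (the standard completion where the normalization is otherwise
unspecified), and the projected context $[C; d]\,W_o^\top$ is
broadcast-added to the map. Attention can sit at the bottleneck alone or
also on every skip connection (per-level weights; sharing them across
levels would couple scales with different channel widths). Training
minimizes the pixel-wise cross-entropy on one-hot labels,
$\mathcal{L} = -\tfrac{1}{HW}\sum_{i,j,c} y_{ijc}\log p_{ijc}$ (log clamped
at $10^{-12}$), with SGD: 20 epochs, batch 32, learning rate 0.1, momentum
0.9, seeded shuffling. The default architecture (depth 4, base 16)
holds roughly 3.4M parameters. The layers are implemented in this package
(im2col + BLAS convolutions with hand-derived backward passes); every
gradient is verified against central finite differences in the test suite.

**Evaluation.** Probability maps are thresholded at 0.5 with ties going to
background (the strict "greater than" reading made deterministic).
Confusion counts, Acc, Sp, Sn, Precision and F1 are computed inside the
FOV only — the de-facto convention for DRIVE-style benchmarks and
consistent with FOV-restricted training. AUC uses the rank (Mann–Whitney)
form, which equals the trapezoidal area over all distinct thresholds, and
is computed per image (a pooled variant is a one-liner on the saved
probability maps). Degenerate denominators return 0 with a `degenerate`
flag instead of an error, so sweep tables never lose rows.

## The synthetic generator

`generate_sample()` emulates the properties that make fundus segmentation
hard: a circular FOV on a dark surround, a brighter background with radial
illumination falloff and Gaussian texture noise, and dark branching vessel
trees (midpoint-displaced centerlines, width decaying per generation from
~8 px trunks to 1 px capillaries, rasterized by distance-to-centerline so
widths are exact). The binary vessel mask is the exact rasterized support,
and an optional central light reflex adds a bright ridge along trunks.
Default geometry gives a vessel fraction of roughly 8–14% of the FOV,
the same order as real fundus vasculature, and guarantees both small-vessel
(≤200 white pixels) and trunk-dominated (>200) windows at 48×48.

What the generator does *not* emulate: pathologies (hemorrhages, exudates),
JPEG artifacts, inter-observer annotation styles, vessel-crossing
geometry, and true capillary tortuosity. Passing tests therefore show that
the pipeline's machinery and its qualitative noise responses are correct,
not that absolute DRIVE/CHASE/STARE numbers are reproduced — those require
the external datasets, supplied via a manifest.

## Desk-scale study sizes

The sweep tests and the acceptance script run a scaled-down study chosen
to exercise the full experimental loop on a laptop-class CPU: 4 training
and 2 test images (160×160), 200 patches per image without rotation
augmentation, a depth-2 U-Net with base width 4 and bottleneck attention,
10 epochs, 3 seed replicates. At this scale the clean baseline reaches an
F1 around 0.8 on held-out synthetic images, leaving headroom for the noise
conditions to separate. The suite checks the qualitative contracts: strong
deformation ($\lambda = 0.8$, $\rho = 1$) depresses Sn and F1 for every
seed; cleaning at $\rho = 0.75$ beats noisy-full training in most seeds;
and F1 falls clearly once noise dominates ($\rho = 1$ at
$\lambda = 0.6$). Below $\rho = 0.5$ the response is flat at seed-noise
resolution — moderate positional deformation can even act as a mild
regularizer — so strict monotonicity of the ratio curve is not guaranteed
at this scale, only the threshold-shaped drop once noisy labels dominate.

## Numerical choices and edge cases

- **Seeding.** Every stochastic stage derives its seed from one run seed
  via `stage_seed(seed, "stage-name")` (a 31-ary string hash folded modulo
  $2^{31}-1$), so sweeps are bit-reproducible on one platform while stages
  remain decorrelated.
- **Rounding** is round-half-away-from-zero wherever intensities or
  coordinates are quantized, stated once and tested.
- **Patch share rounding**: the uniform share is $\lfloor Pn \rfloor$, the
  remainder goes to the small-vessel pool.
- **Empty small-vessel pool** errors by default; `fallback_uniform = TRUE`
  reallocates the share with a warning (synthetic edge cases).
- **Out-of-window deformation sources** (possible only for $\beta < 1$)
  read as background.
- **Constant rasters** abort preprocessing (a z-score of a constant image
  is undefined; silent zeros would poison CLAHE).
- **BN inference** uses running statistics with momentum 0.9; fresh models
  predict with the initialization statistics, which the evaluation tests
  exercise deliberately.
- **Output-prior initialization.** `train_unet()` initializes the final
  layer's bias to the class log-odds of the training labels. Vessel pixels
  are a small minority, and with few SGD steps a zero-initialized head can
  settle into the all-background solution before the vessel class receives
  usable gradient; starting at the prior removes that failure mode without
  touching the optimization protocol. Disable via `prior_bias = FALSE`
  when resuming from trained weights.

## Known limitations

- The grayscale-image probability maps are stored as 16-bit TIFF; PNG
  output is 8-bit in this toolchain.
- GIF masks are not readable; PNG/TIFF/JPEG are.
- The attention "decoder state" is the pooled decoder map; richer readings
  (per-position queries) would square the attention cost at equal benefit
  for maps this small.
- Absolute benchmark numbers on DRIVE/CHASE_DB1/STARE are out of scope for
  the test suite; the harness runs them when a manifest for those datasets
  is supplied.
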