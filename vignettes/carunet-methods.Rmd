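---
title: "carunet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{carunet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carunet)
```

# The problem and the model

`carunet` implements a lightweight convolutional attention residual U-Net
for binary lung-field segmentation of chest radiographs. The input is an
8-bit grayscale image resized to 256 x 256 and rescaled to [0, 1]; the output
is a per-pixel probability map from a sigmoid head, thresholded at 0.5 into a
lung/background mask.

The proposed network is a 4-level encoder-decoder:

* a **stem block** with two concurrent paths — (a) 3x3 convolution, batch
  normalization (BN), LeakyReLU, 3x3 convolution; (b) 1x1 convolution,
  2x2 max pool, nearest-neighbour upsampling — merged by addition, then BN and
  LeakyReLU, followed by a CBAM;
* four stride-2 **residual blocks** in the encoder, each followed by a CBAM.
  A residual block runs BN, a 3x3 depthwise-separable convolution (carrying
  the stride), LeakyReLU, BN, a second separable convolution and LeakyReLU on
  the main path, with a strided 1x1 convolution plus BN shortcut;
* an **ASPP bridge** at 1/16 resolution: four parallel dilated 3x3
  convolutions (rates 1, 6, 12, 18), each with BN, summed elementwise and
  fused by a 1x1 convolution;
* a decoder of four stages, each of which **gates the encoder skip** with an
  additive attention gate (1x1 projections of the pooled skip and of the
  decoder features, LeakyReLU, 1x1 convolution, sigmoid; the single-channel
  gate is bilinearly upsampled and multiplies the skip), bilinearly upsamples
  the decoder features through a 3x3 convolution, concatenates, and applies a
  residual block plus CBAM;
* a 1x1 convolution and sigmoid head.

The **CBAM** here follows the printed equations of the underlying method
rather than the canonical module: channel attention uses global *average*
pooling only (no max-pool path), two fully connected layers (LeakyReLU inside,
sigmoid outside) and a channel-wise multiplication; spatial attention is two
convolutions applied to the channel-gated map (no channel-wise mean/max
concatenation), ending in a single-channel sigmoid map. The gated map
satisfies `|output| <= |input|` elementwise because both gates lie in (0, 1).

The ablation family is assembled by `build_model()` from the same pieces:

| variant          | content |
|------------------|---------|
| `unet`           | classical double-conv U-Net: max-pool encoder, 2x2 transposed-convolution decoder, ReLU, no BN |
| `res_unet`       | residual blocks everywhere, two-residual-block bridge, bilinear+3x3-conv decoder |
| `res_unet_attn`  | `res_unet` plus attention-gated skips |
| `proposed`       | stem + CBAM after every residual block + ASPP bridge + gated skips |

Items IV and V of the ablation differ only in the activation
(`model_config("proposed", activation = "relu")` vs the LeakyReLU default,
slope 0.01); their parameter counts are identical.

# Losses and metrics

The training loss family is the weighted compound
`L = alpha * L_Dice + beta * L_BCE + gamma * L_Focal`, with equal weights
(1, 1, 1) on the enabled terms across all shipped combinations
(`loss_config_by_name("bce+dice")` etc.). The soft Dice loss is
`1 - (2*sum(PG) + eps) / (sum(P) + sum(G) + eps)` with `eps = 1e-6`, which
makes the empty-empty case lossless. Focal loss uses the standard focusing
parameters `focal_gamma = 2`, `focal_alpha = 0.25`; these are deliberately
named `focal_*` because the compound weights already use the plain Greek
names. At `focal_gamma = 0`, `focal_alpha = 1` the focal term reduces exactly
to BCE, which the tests assert.

Evaluation reports accuracy, Dice, IoU, recall, precision and specificity
from the thresholded confusion counts. Per image, `iou = dice / (2 - dice)`
holds identically. Reports aggregate by per-image mean (the table convention
of the underlying study is not stated; the pooled global-confusion variant is
available via `metric_report(..., pooled = TRUE)`). Ratios with an empty
denominator score 1 when the prediction agrees with the empty reference and 0
otherwise.

# Parameter accounting and width calibration

`count_parameters()` uses the standard closed forms — `k*k*Cin*Cout + Cout`
for convolutions, `k*k*Cin + Cin*Cout + Cout` for depthwise-separable
convolutions, `2C` trainable plus `2C` non-trainable (running mean/variance)
per BN layer — and, for a built model, re-derives the same totals by
traversing the actual weight arrays; the two routes must agree exactly and
are tested against each other. Model size is reported as
`total * 4 bytes / 2^20` (single-precision storage, binary megabytes), and
printed "millions" are truncated to two decimals, the only convention
consistent with the published size column.

Published descriptions of this architecture family do not pin per-level channel widths, so the
parameter budgets are the only constraint on them. `calibrate_widths()`
searches base width 8–40 (x2 encoder ladder), the bridge width on an 8-step
grid from `8b + 8` to `32b`, and for the proposed model the CBAM reduction
ratio and spatial divisor in {4, 8, 16}, returning the lexicographically
first configuration inside the target window. The bridge width is a search
dimension of its own because a pure x2 ladder moves in steps of roughly 10^5
parameters per base-width increment — far coarser than the ~2.6k-wide window
that printed two-decimal precision implies. The shipped defaults are the
calibrated results:

```{r budgets}
for (a in c("unet", "res_unet", "res_unet_attn", "proposed")) {
  cat(a, ":", paste(model_config(a)$widths, collapse = "-"),
      "| bridge", model_config(a)$bottleneck, "->",
      format(count_parameters(model_config(a))$total, big.mark = ","),
      "parameters\n")
}
```

For the proposed model the calibration landed on reduction ratio 16 and
spatial divisor 16 (both declared calibration knobs); the attention-gate
intermediate width is half the skip width throughout.

# The synthetic phantom generator

Real radiograph datasets are deliberately out of scope for the test suite, so
`generate_phantom()` produces the minimal structure a lung-field segmenter
must learn: two bright, vertically elongated (axis ratio 1.7–2.3), slightly
inward-rotated (3–8 degrees) ellipses on a darker background (default levels
0.8 vs 0.2), with additive Gaussian noise (sigma 0.05) and optional sinusoidal
rib stripes. The total mask fraction is drawn uniformly from the configured
range (default [0.15, 0.35]) and split equally between the two ellipses;
centres sit near 28% and 72% of the width with small jitter and are pushed
symmetrically apart if the rasterized fields would come closer than three
background columns (a shift preserves the ellipse areas, so the configured
mask fraction is kept to within rasterization error of about one pixel row).
Every pair is a pure function of `(seed, index)` through a counter-based
seed derivation, so datasets are order-independent and reproducible
elementwise.

What the phantoms do **not** emulate: anatomical boundary detail (costophrenic
angles, cardiac silhouette), pathology, intensity inhomogeneity, overlapping
devices, or inter-subject variability. Passing the learning-sanity benchmarks
therefore demonstrates that the optimization machinery and architecture can
fit bimodal bright-field structure — not clinical-grade segmentation
performance, which requires the real datasets and full-scale training.

# Data pipeline conventions

* Preprocessing resizes with bilinear interpolation using half-pixel centres
  and divides by 255.
* The 8:1:1 split computes validation and test sizes as `N/10` rounded
  half-up, with training taking the remainder; this reproduces the published
  per-dataset rows for 662 (530/66/66) and 138 (110/14/14) images. For 247
  images the rule yields (197, 25, 25); the published row (198/25/25) sums to
  248 and cannot be reproduced by any consistent rounding rule, which is
  recorded rather than patched.
* Augmentation plans distribute a fixed budget (default 8000) over the
  training sources with per-source imbalance at most 1, cycling the transform
  list (rotations by -15, 15, -30, 30, -45, 45, -90, 90 degrees; horizontal,
  vertical and double flips; brightness; Gaussian blur) within each source.
  Brightness factors are drawn from [0.8, 1.2] and blur sigmas from
  [0.5, 1.5], both seeded; the publication shows these transforms without
  parameters.
* Geometric transforms use (row, col) 0-based coordinates, rotate
  counter-clockwise for positive angles about the image centre with
  constant-0 fill (so lung fields never duplicate at borders), resample
  images bilinearly and masks by nearest neighbour, and re-binarize masks at
  0.5 as a safety net. Angles that are multiples of 90 degrees use exact
  trigonometric values, so four quarter-turns restore a pair bit-exactly.
* Splitting precedes augmentation: plans are built from training sources
  only, so augmented derivatives can never leak across splits.

# Training

The default regimen follows the published hyperparameters: Adam (beta1 0.9,
beta2 0.999, eps 1e-7), initial learning rate 0.001, batch size 32, 50
epochs, Dice loss, LeakyReLU slope 0.01, learning rate multiplied by 0.1 on a
validation-loss plateau. The plateau patience (5 epochs) and the SGD momentum
(0.9) are unstated in the source and fixed here as declared defaults. The
checkpoint returned by `train_model()` is the epoch with minimum validation
loss. Every stochastic choice (initialization, epoch shuffles, augmentation
jitter, fold assignment, grid-cell seeds) derives from the configured seed
via `derive_seed()`, making runs bit-reproducible; the C++ kernels use no
threading, so results do not depend on BLAS or core count.

Batch normalization uses batch statistics (biased variance) during training
and the running statistics at evaluation time; epsilon is 1e-3. The running
statistics update with momentum 0.5 — deliberately lower than large-scale
framework defaults — because this trainer targets desk-scale regimens with
few optimization steps per epoch: the validation loss that drives
checkpointing and the LR-plateau scheduler is computed with running
statistics, and those must track the moving model within one patience window
(with a high momentum the lagged validation loss can rise while training
improves, spuriously triggering repeated LR reductions).

Weights initialize with Glorot-uniform draws (the default scheme of the
framework stack the original implementation reports), biases at zero, BN at
scale 1 / shift 0. Glorot was chosen over He-style initialization after the
latter saturated the sigmoid head through the stacked residual additions at
build time, which stalls the Dice gradient on the first optimization steps.

The 5-fold cross-validation harness partitions seeded near-equal folds,
trains on the complement of each fold (with a 9:1 internal train/validation
split for checkpoint selection) and reports the per-metric mean and sample
standard deviation. The ablation grid trains one model per (variant, loss,
optimizer) cell from scratch, with the cell index folded into the seed, and
compares each non-reference variant's per-image Dice against the reference
with the Mann-Whitney U test. The U statistic counts pairs with `a_i > b_j`
plus half the ties; p-values are exact by enumeration of all group
assignments of the pooled values whenever `n*m <= 64` (this handles ties
exactly, which the classical distribution does not), and otherwise use the
normal approximation with tie and continuity correction.

# Benchmark problem sizes

The shipped learning benchmarks are sized for a single CPU core: the
overfitting check trains the quarter-width proposed model (widths 3-7-15-30,
bridge 62; about 205k parameters) on eight 64 x 64 phantoms for 200
full-batch steps, and reaches a training Dice above 0.99; the loss-combination
grid runs its seven cells on ten 32 x 32 phantoms at 0.08-width scale for two
epochs each. These sizes are the package's benchmark conditions, chosen so
the whole suite stays comfortably re-runnable; they are not claims about
convergence speed at full scale.

# Known limitations

* The networks process one grayscale channel at a fixed, 16-divisible input
  size; there is no tiling for other geometries.
* Training is CPU-bound R/C++ without data augmentation inside the training
  loop (augmentation happens in the data-preparation stage, as in the
  original workflow).
* The exact stem topology of the source is not recoverable from its text;
  the two-path stem above is this package's declared canonical reading, and
  the published numbering of the attention-combination equation drifts by one
  in the source text (the multiplicative combination is implemented as
  printed).
* Checkpoints are R serialization files (config plus weight arrays), not an
  interchange format.
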