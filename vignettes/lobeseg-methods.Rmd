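---
title: "Methods: automated liver-lobe segmentation and volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated liver-lobe segmentation and volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lobeseg)
```

# The problem

Preoperative volumetry of the right and left hemi-liver, split along the plane
of the central hepatic vein, is required for major hepatic resections and for
donor selection in living-donor liver transplantation. Manual lobe volumetry
on contrast-enhanced CT is slow and examiner-dependent. `lobeseg` implements a
fully automated pipeline: a Multi-Resolution U-Net 3D segments background,
right lobe and left lobe on venous-phase abdominal CT, and a volumetry layer
turns the label maps into milliliter volumes and reader-agreement statistics.

# Data model and preprocessing

Volumes are handled as (z, y, x) arrays with physical spacing `(sx, sy, sz)`
in mm. Ingested HU values are clamped to the 12-bit scanner range
[-1024, 3071]. The working grid is 5 mm slice thickness and a 256 x 256 axial
matrix (physical extents preserved; intensities trilinear, labels
nearest-neighbour).

The network input is a three-channel composite of the same volume seen through
three HU windows: the full 12-bit range (WC 1023.5 / WW 4095), abdominal soft
tissue (WC 40 / WW 400) and liver parenchyma (WC 60 / WW 160), each mapped
linearly to [-1, 1] with clipping, `f(h) = clip((h - WC) / (WW / 2), -1, 1)`.
The window transfer function is the standard linear CT display convention and
all three center/width pairs are run-configuration fields; the defaults are
standard clinical presets. Redundant windows cost three input channels but
present the network with pre-scaled contrast in the ranges that matter.

# t-SDF regression targets

Next to the softmax classification, the network regresses a truncated signed
distance field (t-SDF) per lobe: positive inside the lobe, negative outside,
clipped to +/- 25 mm and rescaled to [-1, 1]. Distances are exact euclidean
distances under anisotropic spacing, computed with a lower-envelope distance
transform (one 1D parabola pass per axis). We use the voxel-center metric: an
inside voxel carries the distance to the nearest *outside voxel center* and
vice versa — the convention that results from shifting the binary mask up by
one and masking a multi-label EDT. The brute-force oracle in the test suite
uses the same convention, so agreement is required to be exact (1e-9 mm), not
approximate. A class absent from a volume yields an all -1 channel; ignore
voxels (see below) count as background for distance purposes, their exclusion
is the loss's job. The 25 mm truncation keeps the regression inside the
receptive field of the network and is configurable.

# Network

The model is a Multi-Resolution U-Net lifted to 3D. Each MultiRes block
factorizes a 7x7x7 receptive field into three chained 3x3x3 convolutions whose
intermediate outputs are concatenated channelwise; a 1x1x1 convolution forms a
residual path: `out = relu(inorm(concat(c1, c2, c3)) + conv1(x))`. The branch
widths split the level's channel budget as 1/6, 1/3 and 1/2 (floored). Skip
connections pass through res-paths — `depth - level` units of
`relu(inorm(conv3(x)) + conv1(x))` — so shallow, early features are processed
before meeting deep decoder features. All normalization is instance
normalization (statistics per channel over the single example), which makes
batch size 1 viable on volumetric crops.

Decisions taken where the design was open:

* **Depth/width defaults** — depth 5, 32 base filters, width multiplier 1.67,
  doubling per level (the original MultiRes recipe). Tests and the desk
  profile use depth 2 with 8 base filters.
* **Upsampling** — a channel-reducing 3x3x3 convolution at the coarse grid
  followed by nearest-neighbour upsampling (a block-constant transposed
  convolution). One upsampling path keeps the hand-written engine small and
  avoids checkerboard artifacts.
* **z pooling** — full 2x2x2 pooling would exhaust a 32-slice crop at depth 5,
  so the z axis is pooled only while it has at least 8 slices (1x2x2 pooling
  below that). The decoder mirrors the recorded factors.
* **Heads** — 1x1x1 convolutions; softmax over the 3 classes, tanh for the 2
  t-SDF channels (matching the [-1, 1] target range).
* **Compute engine** — the environment provides no deep-learning framework for
  R, so the package carries its own reverse-mode engine: compiled kernels for
  convolution, pooling and upsampling plus closed-form backward passes for
  instance norm, softmax and the losses. Every layer is gradient-checked
  against central finite differences in the test suite.

# Objective

The loss is `w_ce * CE + w_dice * GDL + w_l1 * L1` with default weights
(1, 1, 1) (the component weighting is not prescribed; it is a configuration
field). CE is the mean negative log-probability of the true class. GDL is the
generalized soft Dice over all classes including background with class weights
`1/((sum g)^2 + 1e-6)`; the loss is `1 - (2 num + eps) / (den + eps)` so a
perfect one-hot prediction scores exactly 0. L1 is the mean absolute t-SDF
error over all channels; the target is defined everywhere, so it is not
class-masked. Voxels carrying the ignore label (255) are excluded from every
sum — value and gradient — in all three components.

# Training

AdamW at a constant learning rate with decoupled weight decay. The decay is
applied as a multiplicative shrink `p * (1 - wd)` independent of the learning
rate, so `lr = 0, wd > 0` decays weights without taking a gradient step — a
property the tests assert. Reference regime: lr 1e-4, wd 1e-4, batch size 1,
500 epochs of 80 steps (40,000 steps), validation every 10 epochs, fivefold
cross-validation with balanced deterministic splits. Training augmentation per
step: a uniform axial rotation in [-10, 10] degrees (rotation is restricted to
the table axis; the motivation is rotary patient movement), independent
per-axis scales in [0.8, 1.2], then a random 32 x 128 x 128 crop. The t-SDF
targets are interpolated through the geometric transforms rather than
recomputed; with scale factors within 20% of unity the induced distance error
is bounded by 20% of the local distance and treated as augmentation noise.
Out-of-field values: image -1, labels 0, t-SDF -1.

Validation monitoring runs full-volume sliding-window inference on the fold's
validation cases and averages per-class soft Dice; the checkpoint is
overwritten only on improvement, so the stored validation Dice is monotone.

# Inference

Full volumes are predicted with 32-slice windows (full frame in-plane at
256 x 256) and 75% z-overlap (stride 8), the last window snapped to the final
slice; volumes thinner than a window are padded and un-padded. Window
contributions are blended with a plateau/taper profile: full weight on the
central 16 slices and a linear ramp `(i + 1) / (taper + 1)` over 8 slices per
side — near zero but never zero, so every slice keeps influence (a cosine ramp
is available). Aggregation divides by the summed weights explicitly and
renormalizes per voxel. Cross-validation folds are late-fused by averaging
their probability volumes. Hard labels are the per-voxel argmax with ties
resolved toward background.

# Evaluation protocol

The reference standard is a per-voxel majority vote over readers; voxels
without a strict majority receive the ignore label and are excluded from
metrics. Reported metrics per structure (right lobe, left lobe, liver = union
of both): Dice, precision, recall, volume difference VD = pred - ref in ml
(signed; positive = over-prediction; an absolute-difference option exists),
relative volume difference RVD = 100 * VD / ref, Bland-Altman bias and 1.96-sd
limits of agreement, OLS regression of predicted on reference volumes with an
F-test, and Shapiro-Wilk normality of the differences (delegated to
`stats::shapiro.test`). The reader/tool agreement matrix reports pairwise Dice
(mean +/- sd across cases, upper triangle) and volume R-squared (lower
triangle, squared Pearson correlation so it stays defined for two cases);
reader-vs-reader Dice applies no ignore masking since raw annotations carry
none.

# Synthetic phantoms

Patient CT cannot ship with the package, so a generator emulates the study
conditions at desk scale: an anisotropically spaced grid (1.5 x 1.5 x 5 mm)
with a liver-like ellipsoid (~120 HU, venous-phase parenchyma) in soft-tissue
background (~-50 HU), a brighter heart-like blob superior to the liver
(150 HU), a thin diaphragm-like sheet, and Gaussian HU noise (sd 15). The lobe
division is a plane on an oblique in-plane normal with a gentle sinusoidal
bend along z, cut at the projection quantile that realizes the requested
right-lobe volume fraction (default 0.65), so the achieved fraction is exact
to within a voxel shell. Readers are simulated by displacing the liver and
division boundaries with smooth random fields (sd 2 mm) plus occasional
one-slice shifts in the superior third — mimicking the inter-slice ambiguity
near the heart that dominates real reader disagreement.

What the phantoms do *not* emulate: vascular anatomy, neighboring organs with
liver-like HU, contrast-phase variability, scanner artifacts. Passing the
desk-scale pipeline therefore demonstrates that the machinery (preprocessing,
targets, optimization, inference, evaluation) is correct and learnable, not
that clinical accuracy transfers to patient data.

# Desk-scale profile and problem sizes

`default_run_config(scaled_down = TRUE)` switches to a profile sized so the
whole pipeline runs on a single CPU: 24 x 64 x 64 phantoms, 64 x 64 working
axial matrix, depth-2 model with 8 base filters, 16 x 32 x 32 crops, 2 folds,
4 epochs of 80 steps (320 steps) at lr 3e-3 (a tiny network trains stably and
substantially faster at a larger step size than the full-scale 1e-4 regime),
16-slice inference windows with 4-slice tapers. The epoch count is sized to
reach the validation-Dice plateau of the tiny model. The test suite's overfit
check (a capacity test) disables rotation and scaling so it measures
optimization, not robustness to augmentation noise.

# Numerical choices and edge cases

* HU clamp [-1024, 3071] at ingest; windowing clips to [-1, 1].
* Distance transform: exact, anisotropic; degenerate all-foreground /
  all-background masks are rejected in `signed_edt` and handled by the
  absent-class convention (-1 / +1 channels) in `compute_tsdf`.
* CE probabilities are floored at 1e-7 inside the log; GDL uses 1e-6 guards.
* Argmax ties break toward the lower class index (background wins).
* Sliding-window weights are strictly positive, so the explicit sum-of-weights
  normalization can never divide by zero.
* Resampling uses border-clamped sampling for grid changes and constant fill
  for rotations and crop padding (image -1, labels 0, t-SDF -1).
* All randomness (phantoms, readers, folds, initialization, augmentation,
  shuffling) derives from explicit integer seeds via a hash; reruns are
  bit-identical for data and numerically identical for training curves.

# Known limitations

* The engine is CPU-only and sized for desk-scale experiments; the full-scale
  default configuration (depth 5, 256 x 256 windows) is expressible but slow
  without GPU-class hardware.
* t-SDF targets are interpolated, not recomputed, after geometric
  augmentation (bounded approximation, see above).
* Only NIfTI I/O is supported; DICOM series ingestion is out of scope.
* The phantom reader model perturbs boundaries smoothly; it does not simulate
  gross labeling errors or systematic inter-reader bias.
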