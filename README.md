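# lobeseg

Fully automated liver and liver-lobe segmentation and volumetry for
venous-phase abdominal CT, in R.

Preoperative volumetry of the right and left hemi-liver — split along the
plane of the central hepatic vein — is a prerequisite for major liver
resections and for donor selection in living-donor liver transplantation.
Manual lobe volumetry is slow and examiner-dependent. `lobeseg` implements the
complete automated pipeline:

* **NIfTI ingestion** with HU clamping to the 12-bit scanner range, resampling
  to a 5 mm / 256 × 256 working grid;
* **multi-window preprocessing**: three HU windows (full range, abdominal soft
  tissue WC 40/WW 400, liver WC 60/WW 160), each mapped by
  `f(h) = clip((h − WC)/(WW/2), −1, 1)` into a 3-channel composite;
* **Multi-Resolution U-Net 3D** with instance normalization and dual heads:
  softmax over {background, right lobe, left lobe} and a tanh head regressing
  a truncated signed distance field (t-SDF) per lobe — the exact anisotropic
  signed euclidean distance to the lobe boundary, clipped to ±25 mm and
  rescaled to [−1, 1];
* **combined objective** `CE + generalized soft Dice + L1(t-SDF)` with full
  ignore-label support (non-consensus voxels contribute neither value nor
  gradient);
* **AdamW training** (constant lr 1e-4, decoupled weight decay 1e-4, batch
  size 1, 40,000 steps ≙ 500 × 80-step epochs) under fivefold
  cross-validation with seeded augmentation (±10° axial rotation, 80–120%
  per-axis scaling, 32 × 128 × 128 crops);
* **sliding-window inference** (32-slice windows, 75% z-overlap) blended with
  a central-16/taper-8 weight profile and late-fusion ensembling of the fold
  models;
* **volumetry and agreement analytics**: majority-vote standard of reference
  (SoR) with ignore label, Dice / precision / recall, volume difference
  `VD = pred − ref` (ml) and relative volume difference
  `RVD = 100·VD/ref` (%), Bland–Altman bias and limits of agreement, OLS
  regression with F-test, Shapiro–Wilk, and the reader/tool agreement matrix
  (pairwise Dice upper triangle, volume R² lower triangle).

Because patient CT cannot ship with the package, a synthetic phantom module
generates CT-like volumes (liver ellipsoid split by an oblique, gently bent
plane; heart-like and diaphragm-like confounders; HU noise) together with
simulated multi-reader annotations, so every stage is exercisable end-to-end
on one CPU. The package contains its own compiled/auto-differentiated compute
engine (convolution, pooling, instance norm, softmax, AdamW) — every layer is
gradient-checked against finite differences in the test suite.

## Worked example: the desk-scale pipeline

```r
library(lobeseg)

cfg <- default_run_config(scaled_down = TRUE, seed = 42)

cmd_make_phantoms("data/raw", n = 10, seed = 42, config = cfg)
# ... hold out two cases, keep eight in data/train_raw ...
cmd_prepare("data/train_raw", "data/prep", config = cfg)
cmd_train("data/prep", "runs/demo", config = cfg, verbose = TRUE)
#> fold 1 step 320 loss 0.5440 val dice 0.8882
#> fold 2 step 320 loss 1.0343 val dice 0.8864

for (id in c("case_009", "case_010"))
  cmd_predict(file.path("data/raw", paste0(id, "_image.nii.gz")),
              "runs/demo", file.path("pred", paste0(id, "_pred.nii.gz")),
              config = cfg)
report <- cmd_evaluate("pred", "data/raw", "report.json", config = cfg)
```

On the two held-out phantoms this run prints (values from the JSON report):

```
case_009  liver dice 0.9582  rvd  5.44%  | right lobe 0.902  left lobe 0.837
case_010  liver dice 0.9594  rvd  3.17%  | right lobe 0.916  left lobe 0.837
```

i.e. the ensemble recovers the whole liver with Dice ≈ 0.96 and volume errors
of a few percent, over-predicting slightly — the lobes score lower than the
liver because the division plane is the genuinely hard part. `report.json`
additionally carries per-structure Bland–Altman, OLS and the reader/AI
agreement matrix.

The same five commands are available from a shell via the bundled script:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/lobeseg", package="lobeseg"))') \
    train --data data/prep --out runs/demo --scaled-down --seed 42
```

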