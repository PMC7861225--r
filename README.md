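# angioseg

Patch-based 3-D convolutional segmentation of arterial vessels in
time-of-flight (TOF) angiography volumes, for neuroimaging researchers
who need whole-volume vessel masks from raw scans and a fully testable,
dependency-light reference implementation of the multiscale
deep-supervision U-Net family.

Arterial voxels make up only ~0.3–1.5% of a head volume, and bright
non-arterial structures (skull, venous sinuses) invite false positives.
`angioseg` tackles this with voxel-wise classification on patches:

* **Four network variants** built from one declarative configuration —
  a baseline 4-level 3-D U-Net (`unet`, ~6 M parameters), a dual-encoder
  multiscale variant that adds a parameter-disjoint context path on a
  2× larger, average-pooled patch (`context`, ~10 M), a deeply
  supervised variant with auxiliary 1×1×1 sigmoid heads on intermediate
  decoder levels (`ds`), and their combination (`bravenet`).
* **Soft-Dice training**: `loss = 1 − (2Σpg + ε)/(Σp² + Σg² + ε)`, with
  deep-supervision weighting (0.5 on the final head, the rest split
  equally), Adam, Glorot initialisation, patch-level validation
  monitoring and early stopping (patience 3).
* **Vessel-centric sampling**: 2,000 centres per volume inside a
  heuristic air-exclusion mask (16³ box mean, threshold 10), exactly 50%
  centred on vessel voxels; co-centred `[64×64×8]` / `[128×128×16]`
  patch pairs.
* **Stratified 4-fold cross-validation** with a 15% validation carve-out
  per fold (floor-rule stratification by source cohort).
* **Whole-volume inference on raw scans** — no mask, no normalisation
  (an initial batch-normalisation layer learns input statistics) — by
  tiled patch prediction with overlap averaging, strict 0.5
  thresholding, and voxel-wise probability ensembling across fold
  models.
* **Five-metric evaluation**: precision, recall, Dice
  (`2TP/(2TP+FP+FN)`), average Hausdorff distance and 95th-percentile
  Hausdorff distance over all foreground voxels (voxel units by
  default, mm via `spacing`).
* **A synthetic vascular phantom generator** (branching tapered tubes in
  an ellipsoidal head with skull shell, bright unlabelled distractors
  and noise) so the whole pipeline runs and is tested without any
  patient data.

The 3-D convolution engine (im2col + BLAS GEMM, pooling, batch-norm,
nearest-neighbour upsampling, manual backpropagation, Adam) is
implemented natively in C++/R — the package has no deep-learning
framework dependency.

## Worked example

```r
library(angioseg)

# 8 synthetic phantoms from 2 synthetic source cohorts
dat <- generate_dataset(8, phantom_spec(), seed = 1)
dat[[1]]$volume
#> <volume> 128 x 128 x 32 voxels, spacing 0.5 x 0.5 x 0.65 mm,
#>   intensity range [0, 314.8]

# train a compact multiscale network on 6 phantoms
arch <- architecture_config("bravenet", base_width = 8)
gather <- function(ix, n, s0) do.call(c, lapply(ix, function(i) {
  mask <- compute_heuristic_mask(dat[[i]]$volume)
  ctr <- sample_patch_centers(dat[[i]]$labels, mask, n = n, seed = s0 + i)
  sample_patches(dat[[i]]$volume, dat[[i]]$labels, ctr,
                 arch$primary_patch, arch$context_patch)
}))
fit <- train_model(build_network(arch, seed = 11),
                   gather(1:6, 40, 100), gather(1:6, 8, 900),
                   training_config(learning_rate = 1e-2, batch_size = 4,
                                   max_epochs = 4, seed = 7))

# whole-volume prediction on a raw held-out phantom, then evaluation
pred <- binarize(predict_volume(fit$net, dat[[7]]$volume))
evaluate_segmentation(pred, dat[[7]]$labels)
#> <evaluation_report> DSC 0.9040 | precision 0.8822 | recall 0.9268 | AVD 1.8592 | 95HD 22.0000
```

The report reads: 90% Dice overlap with the true vessel tree, 88% of
predicted voxels are true vessels (precision), 93% of true vessel voxels
were found (recall); the foregrounds are on average under two voxels
apart (AVD), with a 95th-percentile nearest-neighbour distance of 22
voxels driven by a few isolated false positives. An untrained network of
the same architecture scores DSC 0.006 on the same phantom.

The full experiment — stratified splits, per-fold training, whole-volume
evaluation, a mean (SD) results table — is one call (here at a reduced
scale that runs in about two minutes; the per-fold training above takes
roughly eight minutes per fold on one CPU):

```r
small_arch <- architecture_config("bravenet", base_width = 4,
                                  primary_patch = c(16, 16, 8),
                                  context_patch = c(32, 32, 16))
cv <- run_cross_validation(dat, small_arch,
                           training_config(learning_rate = 1e-2,
                                           batch_size = 8, max_epochs = 1,
                                           seed = 3),
                           n_centers = 24)
cv$summary      # 5 metric columns, mean and sd rows across folds
```

A thin command-line wrapper covering the same workflow
(`simulate | split | train | predict | ensemble | evaluate | crossval`)
is installed at `inst/cli/angioseg`.

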