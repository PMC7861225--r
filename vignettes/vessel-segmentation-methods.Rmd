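---
title: "Patch-based 3-D vessel segmentation: models, training protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based 3-D vessel segmentation: models, training protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(angioseg)
```

## The segmentation problem

Time-of-flight (TOF) angiography depicts flowing arterial blood as bright
voxels in a 3-D volume without contrast agent. Segmenting the arterial
tree from such volumes is hard for three reasons: whole volumes are too
large to process at once; vessels are extremely sparse (arterial voxels
are roughly 0.3–1.5% of head voxels); and bright non-arterial structures
— the skull, venous sinuses, extracranial tissue — are easily mistaken
for vessels. `angioseg` addresses this with a patch-based voxel-wise
classification framework built around a family of four 3-D
encoder–decoder networks, and ships a synthetic phantom generator so that
every stage is testable without patient data.

## The model family

All four variants share a four-level 3-D U-Net backbone. Each encoder
level applies the sequence *convolution (3×3×3, stride 1) → ReLU →
batch-normalisation* twice (with dropout after the first
batch-normalisation of the level), followed by 2×2×2 max-pooling; channel
widths start at `base_width` (32 by default) and double per level. The
bottom level is followed by two fully connected layers realised as 1×1×1
convolutions (256 channels at the default width). The decoder mirrors the
encoder with parameter-free nearest-neighbour upsampling in place of
pooling and concatenates the corresponding encoder feature maps at each
level. A final 1×1×1 convolution with a voxel-wise sigmoid produces the
probability map. An *initial* batch-normalisation layer is applied to the
raw input, so the network learns its own input normalisation and no
pre-processing of the data is ever needed.

The variants (`architecture_config(variant = ...)`):

* **`unet`** — the baseline above, on `[64 × 64 × 8]` patches.
* **`context`** — adds a second, parameter-disjoint encoder fed with a
  co-centred `[128 × 128 × 16]` context patch, first brought to primary
  dimensions at half resolution by 2×2×2 average pooling. Its bottom
  output is concatenated with the primary bottom before the 1×1×1 layers,
  and its per-level features join every skip concatenation. The context
  path supplies the spatial neighbourhood that a small patch lacks —
  vessels of interest have characteristic anatomical locations.
* **`ds`** — adds deep supervision: the two intermediate decoder levels
  are upsampled to output resolution and given their own 1×1×1 + sigmoid
  prediction heads, whose losses join the training objective. This keeps
  gradients strong in deep layers.
* **`bravenet`** — the full combination of the context path and deep
  supervision.

With the default widths the baseline has ~6.0 million trainable
parameters and the dual-encoder variants ~10.1 million; deep supervision
adds only the 194 parameters of its two extra heads. Counting
conventions: every convolution contributes `27·c_in·c_out + c_out`
scalars (or `c_in·c_out + c_out` for 1×1×1), every batch-norm layer
`2·c`; running statistics are not trainable.

Width choices that the architecture family leaves open were fixed as
follows: `base_width = 32` with per-level doubling, 256-channel bottom
1×1×1 layers, and parameter-free nearest-neighbour upsampling. This
combination reproduces the ~6 M / ~10 M parameter budgets above;
transposed convolutions or other bottom widths would break them. The
layer order inside a sequence is conv → ReLU → BN (not the more common
conv → BN → ReLU); the two bottom 1×1×1 layers are followed by ReLU in
all variants. The dropout rate is configurable and defaults to 0.1. The
sigmoid is the standard `1/(1+exp(-f))`.

## Training loss

Training minimises a soft-Dice loss. For probabilities `p` and binary
truth `g`,

```
soft_dsc(p, g) = (2·Σ p·g + ε) / (Σ p² + Σ g² + ε),    loss = 1 − soft_dsc
```

with stabiliser `ε = 1` by default: half of all training patches are not
vessel-centric and may contain no vessel voxel at all, and the convention
makes the empty/empty case a perfect score instead of 0/0. The analytic
derivative (`soft_dsc_gradient()`) is implemented in closed form and
doubles as an independent oracle for the backpropagation engine; at
`ε = 0` it is exactly

```
∂DSC/∂p_j = 2·[g_j·(Σp² + Σg²) − 2·p_j·Σp·g] / (Σp² + Σg²)².
```

For deeply supervised variants every head contributes its Dice loss,
weighted by `ds_weights()`: 0.5 on the final head, the remaining 0.5
split equally over the intermediate heads.

## Sampling and cross-validation protocol

Training patches are drawn only inside a *heuristic mask*: the volume is
smoothed with a 16³ sliding box mean (stride 1, replicate edge padding)
and thresholded strictly at intensity 10. This keeps the head plus a
thick border band around the skull — border patches are important
training material — while excluding patches of pure air. The mask is a
training-time device only; inference never uses it. Per volume, 2,000
centres are sampled by default, exactly half of them vessel-centric (the
centre voxel itself is labelled vessel). The vessel quota is drawn from
vessel voxels, the remainder from background mask voxels, each without
replacement while the pool allows and with replacement otherwise. Primary
`[64×64×8]` and context `[128×128×16]` patches are extracted around the
same centre with zero padding at volume borders; even-sized patches place
the centre at offset `size/2` (the upper-middle voxel), a convention used
identically everywhere, including the tiling of whole-volume inference.

`make_cv_splits()` builds stratified k-fold splits: per source cohort,
each fold's test set receives `floor(count/folds)` ids; the remainder
stays in training across all folds. From each fold's non-test pool,
`floor(0.15·pool)` ids move to validation, stratified per source by the
same floor rule with any shortfall taken from the largest cohort. On
cohort sizes (74, 9, 181) with 4 folds this yields exactly 170 training,
29 validation and 65 test ids per fold.

Training uses Adam on Glorot-uniform-initialised weights, monitors the
patch-level validation loss after every epoch (in inference mode, i.e.
with batch-norm running statistics), stops early after 3 epochs without
improvement, and returns the weights of the best validation epoch.
Candidate learning rates {1e-2, 1e-3, 1e-4} are compared by mean
whole-volume validation Dice across folds (`select_learning_rate()`,
ties toward the smaller rate, applied globally over candidates rather
than nested per fold). Patch centres are drawn once per volume per
experiment, not re-drawn per epoch, which keeps runs exactly
reproducible under their seed; validation centres use an independent
seed. Batch-norm running statistics use momentum 0.9 so that they track
the current weights closely even in short trainings.

## Whole-volume inference

`predict_volume()` tiles the volume with patch-sized steps (stride
configurable; components larger than the patch are capped to preserve
coverage), clamps the last tile per axis to the boundary, zero-pads
patches that overhang the volume, runs the network, and writes the final
head's probabilities back; voxels covered by overlapping tiles receive
the mean of all contributing predictions. Binarisation is strict
(`p > 0.5`; ties map to background). `ensemble_predict()` averages the
probability maps of several (e.g. per-fold) models voxel-wise before
thresholding. Inference consumes raw volumes — no mask, no
normalisation, no post-processing.

## Evaluation metrics

`evaluate_segmentation()` reports precision, recall, Dice, the average
Hausdorff distance (AVD: the maximum of the two directed mean
nearest-neighbour distances) and the 95th-percentile Hausdorff distance
(95HD), the latter two over *all* foreground voxels rather than extracted
surfaces, in voxel units by default with a physical-mm mode via the
`spacing` argument. Percentiles use linear interpolation between order
statistics. Degenerate cases: with both foregrounds empty the distances
are 0 and the overlap metrics 1; with exactly one empty the distances are
`Inf` (with a warning), and an overlap metric whose denominator is empty
is 1 by vacuous truth. Nearest-neighbour distances are computed by an
exact C++ scan over the foreground coordinate sets, which at the
foreground sizes arising here (10³–10⁴ voxels) is fast and avoids any
approximation; the test suite checks every metric against naive
double-loop oracles.

## The phantom generator

`generate_dataset()` produces TOF-like volumes with known ground truth.
Geometry: an ellipsoidal head (semi-axes 0.44 of the volume shape — an
inscribed ellipsoid cannot exceed ~52% of the volume, so this is as
head-filling as a skull shell allows) of tissue intensity 80, surrounded
by a skull shell at 120 and near-zero air at 2; vessel trees grown by a
direction-persistent branching random walk, rasterised as tubes with
radii tapering monotonically from 3 to 0.8 voxels, repeated until the
vessel fraction within the head reaches the target (0.8% by default,
within the physiological 0.3–1.5% bracket); bright unlabelled distractor
blobs at intensity 250 as venous/extracranial analogues; additive
Gaussian noise (σ = 5, which keeps zero-clipped air means well below the
mask threshold of 10, honouring the air/head separation the mask relies
on); negative intensities clipped at zero. Volumes default to
128×128×32 voxels of 0.5×0.5×0.65 mm.

What the phantoms do and do not emulate: they reproduce the salient
difficulty sources — sparse tubular foreground, bright border shell,
bright non-vessel distractors, raw unnormalised intensities — but not MR
flow physics, Rician noise, intensity inhomogeneity, or anatomical
vessel topology. Tests passing on phantoms therefore demonstrate that
the machinery is correct and that the networks can learn vessel-like
structure from realistic sparsity; they do not certify clinical
performance.

## Desk-scale problem sizes

The test suite runs the full pipeline at sizes chosen for a single CPU:
the end-to-end check trains a `base_width = 8` `bravenet` on 6 phantoms
(40 training + 8 validation centres per volume, batch 4, learning rate
1e-2, at most 4 epochs) and evaluates whole-volume Dice on 2 held-out
phantoms; the cross-validation driver is exercised on 16×16×8 patches
with a `base_width = 4` network. Unit tests use miniature configurations
(`base_width` 2, 16×16×8 patches) throughout. The quadratic scaling of
parameter count in width makes these reductions cheap while exercising
identical code paths.

## Numerical choices and limitations

* The convolution engine computes im2col + GEMM in single precision
  (the standard precision of deep-learning practice); parameters and all
  other arithmetic are double. Gradient checks in the suite use
  tolerances appropriate to that mix, and the loss-gradient oracle is
  checked in pure double precision at 1e-4 relative.
* Batch-norm uses ε = 1e-5; Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-7.
* With an 8-slice patch and three pooling steps the bottom z-extent is 1;
  all kernels handle degenerate extents.
* Max-pooling ties resolve to the first voxel in x-fastest order;
  binarisation and masking thresholds are strict comparisons.
* The tiling, overlap handling and ensemble averaging of whole-volume
  reconstruction are this package's own choices (non-overlapping tiles
  by default, mean aggregation on overlap); alternatives can be had via
  the `stride` argument.
* Sampling centres with replacement only under pool exhaustion, the
  upper-middle centre convention for even patches, and the global (not
  per-fold) learning-rate selection are documented fixed choices where
  several readings were defensible.
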