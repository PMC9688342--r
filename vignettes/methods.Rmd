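---
title: "Segmenting elective lymph node levels I-V: models, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting elective lymph node levels I-V: models, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lnlevelseg)
```

## The problem

In head-and-neck radiotherapy the elective target volume is built from
anatomically defined compartments of cervical lymph nodes — levels I-V —
contoured on the planning CT. Manual contouring is slow and shows
substantial inter-observer variation, and because different primaries call
for different level combinations, a segmentation of *individual* levels is
more flexible than a single combined structure. The task is hard in a
specific way: the levels are defined by guideline rules on axial slices
(levels II, III and IV never coexist on one axial plane), not by visible
tissue boundaries, so a model must learn geometric conventions as much as
image appearance, and patient pitch/tilt confounds those conventions.

`lnlevelseg` implements three configurations for this task on 3D CT
volumes with voxel labels 0 (background) and 1-5 (levels I-V):

* **C1 (UNet)** — a residual, patch-based 3D UNet with M = 6 output
  classes segments background and the five levels directly, with
  sliding-window inference over the whole volume.
* **C2 (MV)** — a 2.5D multi-view, multi-scale CNN classifies every voxel
  inside a pre-constructed evaluation mask (the manual reference expanded
  by 15 mm) into the six classes.
* **C3 (UNet+MV)** — a binary (M = 2) UNet first segments the combined
  I-V structure; after post-processing, the multi-view network (M = 5)
  relabels each foreground voxel into a level. The relabeling stage can
  neither add nor remove foreground, which removes the systematic
  foreground over-estimation a standalone voxel classifier exhibits.

## Data model and pre-processing

Volumes are 3D scalar grids with physical spacing and origin in mm
(voxel `(i,j,k)`, 0-based, sits at `origin + c(i,j,k) * spacing`); label
maps share the geometry. NIfTI (`.nii`/`.nii.gz`) is the single on-disk
format. All geometry (margins, distances, patch truncation) is computed
in mm, never voxels.

Everything is resampled to isotropic 1.25 mm voxels before training and
inference: intensities with a 3rd-order (cubic B-spline) interpolant —
the volume is prefiltered into spline coefficients with mirror boundaries
and then sampled on the new grid — and label maps with nearest-neighbour
interpolation, which can never invent labels. Intensities are normalized
to [0, 1] by a linear clamped window with center 0 HU and width 700 HU
(`windowSetting()`), the soft-tissue window in which nodal anatomy lives;
values at or below center - width/2 map to 0, at or above center +
width/2 map to 1.

## Patch sampling

Training patches (64^3 voxels at full scale) are drawn from two
unilateral regions of interest of 280 x 200 x 280 mm placed on the
lateral halves of the volume and clamped to the volume bounds. Patch
centers follow a per-axis truncated normal law: the mean and standard
deviation are the per-axis moments (population estimator, divide by N)
of the per-case centers of mass of the combined I-V structure inside the
ROI, and the law is truncated — by inverse-CDF sampling, so no rejection
loop is needed and termination is guaranteed — to the interval that
keeps the whole patch inside the clamped ROI. This concentrates patches
where foreground actually lives, which keeps the soft Dice loss
well-conditioned (patches with no foreground make the Dice denominator
degenerate).

Augmentation is applied on the fly: left-right flipping with probability
0.5; rotation with probability 0.4, in the sagittal or transversal plane
(fair coin) by an angle uniform on [-5, +5] degrees, cubic interpolation
for the image and nearest-neighbour for labels; contrast adaptation with
probability 0.4, drawing a new window center ~ N(0, 21 HU) and width ~
N(700, 21 HU) (21 HU = 3% of the default width). Geometric transforms
act on the raw HU patch and the (possibly re-drawn) window is applied
last, so the sampled window is always the effective one and augmented
images stay in [0, 1].

## Networks

**Residual 3D UNet** (`unetSpec()`, `buildUNet()`): a stem convolution,
then `depth` encoder levels of residual blocks — two 3x3x3 convolutions,
each followed by batch normalization *before* the ReLU, with an identity
shortcut (1x1x1 projection + BN when the channel count changes) — and
2x max-pooling between levels. The decoder upsamples by
nearest-neighbour, concatenates the encoder skip, fuses with a 1x1x1
convolution and refines with one 3x3x3 convolution (both BN + ReLU),
and a 1x1x1 head produces a per-voxel softmax over M classes. Defaults:
depth 4, 16 base filters doubling per level, spatial (channel-wise)
dropout 0.1 on the bottleneck during training only. The published
description fixes the residual blocks, BN-before-activation, 64^3
patches and the class counts; filter counts and depth are not printed,
so they are package defaults and fully configurable. Channel-wise
dropout (dropping whole feature maps) is used rather than elementwise
dropout, the standard choice for convolutional feature maps.

**Multi-view 2.5D classifier** (`mvSpec()`, `buildMV()`,
`extractViews()`): for a query voxel, three orthogonal in-plane views
(axial, sagittal, coronal) are extracted at three context pyramid
scales, sampling every, every other and every fourth voxel, so 32
in-plane samples at 1.25 mm span 4, 8 and 16 cm. Out-of-volume samples
replicate the nearest edge voxel. Each of the nine views has its own
stack of 3x3 2D convolutions (BN before ReLU, 2x pooling); the view
features of all scales are concatenated and fused by a dense layer
feeding the M-class softmax. Views do not share weights (the published
schematic is ambiguous; independent weights are the more general
default).

Both networks run deterministically at inference: dropout off, batch
normalization on running statistics.

The numerical engine is implemented in the package itself (C++ behind
R wrappers): convolutions as single-precision im2col + BLAS `sgemm`
with hand-derived backward passes, batch-norm statistics accumulated in
double precision, and a persistent engine object for the UNet so a
training step costs one R/C++ round trip. An independent R
implementation of the same forward/backward pass ships in the package
and the test suite cross-checks the two against each other and against
finite differences.

## Losses

For the UNet, the multi-class soft Dice loss is the weighted sum over
foreground classes of `DL_m = 1 - 2|A_m . B_m| / (|A_m| + |B_m| + eps)`,
computed on softmax probabilities (soft Dice), with `eps = 1e-5` added
to the denominator only — this preserves `DL = 1` for disjoint masks
while guarding the otherwise unconstrained denominator. With one
foreground class and unit weight it reduces exactly to the binary Dice
loss used by the C3 foreground stage. Class weights are
inverse-frequency balanced over foreground voxels of the training
cases: `W_m = N_total / (M_fg * N_m)` (background excluded from all
sums; equally frequent classes give weights of exactly 1).

The multi-view network minimizes categorical cross-entropy
`H(p, q) = -sum p log q` against one-hot references, with `q` clipped to
`[1e-7, 1 - 1e-7]` before the log.

## Training

Adam (learning rate 0.001, beta1 0.9, beta2 0.999, epsilon 1e-7) with an
exponential schedule that decays the rate by 5% per epoch down to a
floor of 1e-4 (`lrSchedule()`). An "epoch" for the patch-based UNet is
4096 sampled pairs (about 34 patches per side per patient over 60
bilateral cases) — the notion is arbitrary in a patch-based setting and
the budget is configurable. The multi-view network trains on voxel
pairs: each epoch draws a fresh random subset of at most 20% of the
pooled training voxels (an upper bound; desk-scale runs may draw less
via `maxPairsPerEpoch`) and oversamples minority classes to equal
counts, in minibatches of 32. Cross-validation uses seeded 5-fold
partitions (`makeFolds()`; 60 cases give 48/12 splits). After every
epoch a validation DSC is computed on patches (UNet) or voxels (MV)
sampled from validation cases held out of the training split — carved
from the training cases, not the test fold, to avoid leakage — and the
checkpoint with the *highest* validation DSC is kept, not the last.
Ensembles are `nMembers` sequentially trained networks whose seeds
derive deterministically from a base seed; at inference the members'
class probabilities are summed and the argmax decides the label, with
ties broken toward the lower class index (background wins ties).

## Inference and post-processing

Full volumes are segmented by sliding the UNet's field of view (edge P)
with stride P/2 and keeping only the central (P/2)^3 voxels of each
window, so every voxel is classified exactly once with context on all
sides. The volume is replicate-padded by P/4 plus whatever rounds each
axis up to a multiple of P/2, so the central tiles exactly cover the
original grid (the padding convention is a package choice; the
published rule fixes the 64/32/32^3 arithmetic).

The combined I-V structure of every segmentation is post-processed:
interior holes (background not 6-connected to the grid border) are
filled, then all but the largest 26-connected component is removed;
filled voxels take the majority level of their 26-neighbourhood.
3D (volumetric) hole filling is used; the published description does
not distinguish 2D slice-wise from 3D filling, and 3D is the stricter,
orientation-independent choice. In C3 this post-processing runs on the
binary UNet output *before* the multi-view relabeling, so the final
foreground set is exactly the post-processed UNet foreground.

PTVs are derived by expanding the union of selected levels (I-V, or
II-IV) by an exact Euclidean 4 mm margin; the 15 mm evaluation mask of
C2 is the same exact-Euclidean expansion of the manual reference.
Distances use an exact anisotropic Euclidean distance transform
(separable lower-envelope algorithm), not voxel-count dilation. Note
that C2's mask derives from the manual reference at test time, as in
the original protocol, which leaks reference extent information into
C2's evaluation; C3 replaces it with the UNet foreground.

Evaluation metrics (`segmentationReport()`): Dice (1 for two empty
masks, 0 when exactly one is empty), exact Hausdorff distance (100th
percentile by default; HD95 available), symmetric mean surface distance
(mean of the two directed means), per-structure volumes, volume outside
the reference (mL), and ICC(3,1) — two-way mixed effects, single
measurement, consistency — for volumetric agreement across cases.
Surfaces are foreground voxels with 6-connectivity exposure, counting
the grid border as exposure. Paired model comparison (Wilcoxon
signed-rank, Bonferroni) is available as a thin wrapper
(`compareModels()`) around the standard tests; it is a report column,
not part of the core evaluation.

## The synthetic phantom

Clinical CT with per-level reference contours cannot ship with a
package, so `generatePhantom()` builds a desk-scale stand-in: a
128 x 128 x 160 grid at 1.25 mm with an elliptical soft-tissue body
(about 40 HU, Gaussian noise sd 20 HU, default semi-axes 38 x 34 mm),
air background (-1000 HU), a bone-like midline cylinder (700 HU) as a
landmark, and bilateral level structures (about 70 HU) mirrored about
the sagittal midplane. Levels II, III and IV are stacked
cranio-caudally as adjacent slabs sharing a lateral band — so, without
angulation, no axial slice contains more than one of them, mimicking
the guideline constraint. Level I sits anterior-cranial and reaches
the midline (the submental compartment is a midline structure), which
joins the two sides into one combined structure, and level V lies
posterior. Default cranio-caudal extents are 20 mm for levels I-IV and
40 mm for level V.

Two properties of the geometry are deliberate. First, the phantom's
proportions follow the structure-to-patch ratio of the clinical setup
rather than absolute neck dimensions: the level structures are
superficial and the body narrow enough that patches sampled around the
structures also contain air, bone and body borders — as patches from a
real planning CT do. A network trained on patches that never see a
tissue class cannot be expected to reject it at whole-volume
inference. Second, each phantom's assembly is shifted by a
seed-dependent uniform positioning jitter (up to 4/6/18 mm laterally/
antero-posteriorly/cranio-caudally). This emulates inter-patient
variability in anatomy and scan positioning and matters
methodologically: the Gaussian patch sampler's spread is the
across-case standard deviation of center-of-mass positions, which in a
real cohort is driven by exactly this variability. Identical geometry
across cases would degenerate the sampler (sd = 0) in a way no real
cohort does. The jitter moves but does not rescale the structures, so
the labelled volume is stable across seeds (within voxelization).

What the phantom does *not* emulate: real soft-tissue texture and
organ boundaries, contrast agents, pathological nodes, the
guideline-driven dependence of level borders on bony landmarks, and
realistic inter-observer contouring noise. Passing the end-to-end
phantom tests therefore demonstrates that the pipeline is wired
correctly and can learn and reproduce geometric label conventions from
images — not that the clinical accuracies reported for real cohorts
are reproduced.

`angulate()` applies rigid pitch/tilt (cubic for intensities, nearest-
neighbour for labels) to emulate the angulation confounder; a 10 degree
pitch makes levels II and III share axial slices, the situation that
breaks slice-based contouring rules.

## Desk-scale experiment sizes

The package's self-contained experiment (`runPhantomExperiment()`,
also driven by `scripts/acceptance.R` and the acceptance test) uses a
3-member ensemble of binary UNets with 8 base filters and depth 3 on
32^3 patches, 256 pairs per epoch, 10 epochs, batch size 8, trained on
10 phantoms with 2 more for checkpoint validation and evaluated on 4
held-out phantoms; the sequential stage uses a small multi-view network
(8 in-plane samples, 2 conv layers per view) trained on foreground
voxels for 3 epochs. The sampling ROIs use a 100 mm lateral extent
because the phantom (160 mm across) is narrower than two clinical
280 mm ROIs; anterior-posterior and cranio-caudal extents keep the
clinical 200/280 mm. These sizes are the package's chosen desk-scale
study conditions; the full-scale defaults (64^3 patches, depth 4, 16
filters, 4096 pairs, 100 epochs, 5 members) remain the function
defaults.

## Numerical choices and degenerate inputs

* Argmax ties break toward the lower class index everywhere, so
  background wins ties with foreground; deterministic by construction.
* The Dice smoothing `eps = 1e-5` sits in the denominator only
  (configurable); the CCE clip is `1e-7`.
* Batch-norm uses eps 1e-3 and momentum 0.9 for running statistics.
* Empty masks: DSC of two empty masks is 1, of one empty mask 0;
  HD/MSD on an empty mask are reported as missing; an empty evaluation
  mask yields an all-background probability map with a warning; empty
  foreground passes through post-processing unchanged with a warning.
* ICC is undefined for constant measurements and returned as missing
  with a warning.
* The truncated-normal sampler handles sd = 0 as a point mass at the
  (interval-clamped) mean.
* Mirror boundaries for the spline prefilter use the exact closed-form
  initialization when the axis is shorter than the filter horizon.

## Limitations

The clinical results of the underlying approach require a real
multi-patient CT cohort and GPU-scale training; this package reproduces
the method and its machinery, verified end-to-end at phantom scale on a
CPU. The single-precision engine means gradients match an independent
double-precision implementation only to about the float rounding level,
and pooling ties can reroute individual gradient entries. DICOM-RT
structure sets are out of scope (NIfTI only), as are levels VI-VII,
dose-volume analysis, and test-time augmentation.
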