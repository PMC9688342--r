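# lnlevelseg

Automated segmentation of the elective cervical lymph node levels I–V on
3D CT volumes, for radiotherapy target definition. The package is aimed
at researchers in medical image analysis and radiation oncology who want
a self-contained, CPU-runnable implementation of three deep-learning
configurations for this task, together with the full training, inference,
post-processing and evaluation machinery and a synthetic neck phantom so
every stage can be exercised without clinical data.

## The method

Voxels of a CT volume (isotropically resampled to 1.25 mm, intensity
windowed with center/width 0/700 HU onto [0, 1]) are labelled 0
(background) or 1–5 (levels I–V) by one of three configurations:

* **C1 — UNet.** A residual, patch-based 3D UNet (3×3×3 convolutions,
  batch normalization before every activation, residual blocks, M = 6
  softmax classes) trained on 64³ patches drawn from unilateral
  280×200×280 mm regions of interest by a truncated-Gaussian sampler
  whose moments come from the per-case centers of mass of the combined
  I–V structure. The training loss is the class-weighted multi-class
  soft Dice loss

  DSC_loss = Σₘ Wₘ · DLₘ,  DLₘ = 1 − 2|Aₘ∩Bₘ| / (|Aₘ|+|Bₘ|+ε),

  with inverse-frequency weights Wₘ over foreground classes. Full
  volumes are segmented by sliding the 64³ field of view with stride 32
  and keeping the central 32³ voxels of every window, so each voxel is
  classified exactly once.

* **C2 — MV.** A 2.5D multi-view network classifies each voxel of an
  evaluation mask (the manual reference expanded by an exact Euclidean
  15 mm margin) from three orthogonal 2D views at three pyramid scales
  spanning 4, 8 and 16 cm, trained with categorical cross-entropy
  H(p,q) = −Σₘ Σₐ p(a,m) log q(a,m) on per-epoch subsets of at most 20 %
  of the voxel pool with minority oversampling.

* **C3 — UNet+MV.** A binary UNet segments the combined I–V structure;
  after post-processing (3D hole filling, then keeping the largest
  26-connected component), the multi-view network relabels each
  foreground voxel into one of the five levels. The relabeling stage
  preserves the foreground set exactly.

Training uses Adam (lr 0.001, 5 %/epoch exponential decay to 1e-4),
seeded 5-fold cross-validation (60 cases → 48/12 splits), best-
validation-DSC checkpointing and ensembles of sequentially trained
networks fused by summed class probability. Evaluation reports Dice,
exact Hausdorff distance, mean surface distance, volumes, volume outside
the reference, ICC(3,1) for volumetric agreement, and the 4 mm PTV
expansions PI–PV and PII–PIV.

There is no deep-learning framework dependency: the convolutional
engine (forward and backward) is implemented in the package in C++
(single-precision im2col + BLAS sgemm) with an independent R reference
implementation cross-checked in the tests.

## Worked example

Generate a synthetic neck phantom, tilt the patient by 8° of pitch, and
evaluate the tilted labels against the upright reference — a direct look
at how much pure angulation degrades slice-defined level structures:

```r
library(lnlevelseg)
ph  <- generatePhantom(phantomSpec(seed = 42))
ph$labels
#> LabelVolume 128 x 128 x 160, 6 classes, spacing 1.25 x 1.25 x 1.25 mm
#>   voxels per class: 0=2584576 1=7744 2=6656 3=6656 4=6656 5=9152
rot <- angulate(ph$volume, ph$labels, pitchDeg = 8, tiltDeg = 0)
segmentationReport(rot$labels, ph$labels)
#>   structure   dsc   hd   msd volPred volRef volOutside
#> 1         I 0.744 3.95 1.806    15.1   15.1       3.87
#> 2        II 0.883 2.50 0.733    13.0   13.0       1.52
#> 3       III 0.920 2.50 0.498    13.1   13.0       1.07
#> 4        IV 0.785 5.00 1.360    13.0   13.0       2.79
#> 5         V 0.809 4.51 1.202    18.0   17.9       3.50
#> 6       I-V 0.882 5.00 0.993    72.2   72.0       8.60
#> 7     PI-PV 0.912 5.00 1.120   144.2  143.1      13.19
#> 8   PII-PIV 0.910 5.00 1.020    84.6   83.9       7.86
```

Eight degrees of pitch alone push individual-level Dice down to
0.74–0.92 (hardest for the small, cranio-caudally thin levels), leave
up to 5 mm of worst-case surface error, and put ~8.6 mL of the
combined structure outside the upright contour — the angulation
confounder in numbers.

Training an ensemble and segmenting a volume end-to-end:

```r
cases <- lapply(1:10, function(i) generatePhantom(phantomSpec(seed = i)))
val   <- lapply(11:12, function(i) generatePhantom(phantomSpec(seed = i)))
spec  <- unetSpec(patchSize = 32, depth = 3, baseFilters = 8, nClasses = 2)
ens   <- trainEnsemble(trainUNet, spec, cases, val, nMembers = 3,
                       epochs = 10, pairsPerEpoch = 256, batchSize = 8,
                       roiExtent = c(100, 200, 280))
test  <- generatePhantom(phantomSpec(seed = 99))
maps  <- lapply(ensembleMembers(ens), slidingWindowPredict, vol = test$volume)
seg   <- postprocessCombined(ensembleFuse(maps))
dsc(seg, binarizeLabels(test$labels))
```

`runPhantomExperiment()` packages exactly this experiment (plus the C3
relabeling stage) with fixed desk-scale sizes.

A thin command-line wrapper for phantom generation, prediction and
evaluation ships in `inst/cli/lnlevelseg.R`:

```sh
Rscript inst/cli/lnlevelseg.R phantom  --out phantom/
Rscript inst/cli/lnlevelseg.R evaluate --pred seg.nii.gz --ref ref.nii.gz \
        --out report.csv
```

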