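---
title: "Automated vascular calcification scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated vascular calcification scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Arterial calcification burden in the abdominal aorta and lower-extremity
arteries is a clinically meaningful marker of cardiovascular risk,
particularly in peripheral arterial disease. The reference measurement is
manual: a reader converts a contrast-enhanced CT angiogram (CTA) to the
8-bit intensity scale, outlines the artery of interest on every
transverse slice from just below the left renal artery down to the knee,
applies an intensity threshold that separates calcified wall from
contrast-filled lumen, and counts the voxels above it. `vasccalc`
automates that protocol: a convolutional encoder–decoder segments the
vascular system slice by slice, the predicted mask is multiplied into the
image to isolate the vessels, voxels above the threshold are counted per
slice over the anatomical range, and the count is converted to a volume
with the voxel-size conversion factor dx·dy·dz.

Clinical CTAs are not shipped with this package, so the whole pipeline is
exercised on synthetic phantoms with analytically known truth (below).
The phantom generator is first-class, tested code — it is the package's
evidence that the measurement chain is exact where exactness is provable,
and well-behaved where only statistical agreement is possible.

## The segmentation model

The network is a U-Net-style encoder–decoder. The encoder is a residual
stack with five downsampling stages (stride-2 convolutions; each stage a
residual block with a projection shortcut), so the input side length must
be divisible by 2^5 = 32. Four skip connections are taken from the first
four stages. The decoder has five blocks; each upsamples by two
(nearest-neighbour), concatenates the matching encoder feature where one
exists (the fifth and final block, back at full resolution, has none),
and applies conv → batch-norm → ReLU twice. A 1×1 convolution and a
sigmoid produce a per-pixel vessel probability; the sigmoid lives in the
model and the loss operates in probability space. Grayscale input is
duplicated into three channels, the convention inherited from encoders
designed as RGB classifiers, which keeps the first-layer shape compatible
with externally pretrained weights.

Pretrained encoder weights are an optional hook (`model_config(pretrained =
...)` loads a checkpoint); the default is He initialization from the
config seed. The tested content of this package is the architecture and
the measurement chain, not any particular weight set. `base_channels`
scales the width; the default of 8 is a desk-scale model
(~55k parameters at width 4, ~880k at width 16) that trains on one CPU
in minutes while keeping the exact block structure of a full-width model.

Training minimizes `BCE + (1 − softIOU)` with unit weights. The soft IOU
uses `sum(p·t)` as intersection and `sum(p) + sum(t) − intersection` as
union, so on hard {0,1} predictions the Jaccard term equals one minus the
confusion-count IOU exactly — a property the tests assert. The optimizer
is Adam at learning rate 1e-3 with batch size 15 in the full recipe
(desk-scale runs use 8). Validation IOU (mean per-slice IOU of the
binarized prediction) is computed after every epoch and the
best-validation checkpoint is returned; there is no early stopping.
Desk-scale training from random initialization has genuine run-to-run
variance — a small fraction of initializations converge to solutions
that segment the bone confounder as vessel — so `train_fold()` supports
a standard validation-based restart: when the best validation IOU of a
run falls below `restart_threshold`, training restarts from a fresh,
deterministically derived initialization (up to `max_restarts` times)
and the attempt with the best validation IOU is kept. Selection uses
validation data only; held-out test patients are never consulted.

Two readings of "train once, fine-tune per fold" exist for
cross-validated training; `vasccalc` defaults to fully independent
per-fold training (the leakage-safe reading) and offers
`training_config(warm_start = TRUE)` for the sequential reading.
Validation data comes from the training side of each fold: the last
training patient is held out, since no validation fraction is prescribed
by the protocol. Folds always split patients, never slices:
`make_folds()` enforces disjoint test sets covering every patient
exactly once (11 patients split 3/3/3/2 with the defaults).

## Augmentation

`augment_pair()` mirrors a standard medical-image augmentation recipe:
histogram equalization, CLAHE (contrast limit 0.4), box blur with kernel
size drawn from {3, 5, 7}, horizontal flip with probability 0.25, grid
distortion (5×5 control grid, per-node limit 0.3 of a cell) with
probability 0.70, and downscale–rescale to 60–90% with probability 0.30,
plus brightness/contrast jitter. Photometric steps fire with probability
0.5 each, the customary library default where none is stated.

Geometric transforms are applied identically to image and mask — the mask
resampled nearest-neighbour so it stays binary — while photometric
transforms touch the image only. A literal joint application of
equalization or jitter to a {0,1} mask would destroy its meaning, so
"applied to both" is interpreted as applying to the *pair*, with each
transform acting on the representations it is defined on. Saturation and
hue jitter are accepted in the config but are inert on single-channel
grayscale. Dataset expansion appends `multiplicity` (default 3)
augmented copies per original slice.

## Calcium scoring

Scoring operates on the 0–255 8-bit scale. `hu_to_8bit()` converts
Hounsfield-unit volumes by a linear window map with round-half-up
rounding; the default window is the volume's own min–max (the common
whole-range 8-bit conversion), and a fixed window can be pinned for
cross-patient comparability since the manual protocol does not specify
one. The map is monotone for every window, and a degenerate window maps
to 0 by convention.

The threshold default is 145, the value established by double-blind
reading as the lowest intensity that includes calcified wall without
selecting contrast-filled lumen. "Exceeds the threshold" is implemented
as a strict inequality, with `inclusive = TRUE` covering the non-strict
reading — at integer intensities the two differ by exactly the voxels
sitting on the threshold. The Agatston-style minimum component area
(8-connectivity within each 2-D slice, area in mm² from the pixel
spacing) is implemented but off by default: the automated protocol counts
all above-threshold voxels, and the area rule belongs to the clinical
coronary score this method is analogous to, not to the method itself.
Counting is per 2-D slice with no 3-D connectivity, matching the manual
voxel-counting workflow. The scoring start slice (the anatomical renal
landmark) cannot be detected automatically and is a required input,
carried by phantom truth as `start_slice`.

Volume conversion is `total_count × dx·dy·dz` from the container header —
the report carries counts, the voxel volume and mm³ so either unit
convention is recoverable.

## The phantom generator

Each phantom is a stack of square slices containing one continuous
vessel: a bright lumen disk (contrast-enhanced blood) inside a darker
wall annulus, following a smoothly drifting centreline with a mildly
tapering radius; calcified arcs are annular sectors embedded in the wall;
bone-like disks of overlapping intensity act as confounders; optional
artifacts emulate the known clinical failure modes (no contrast injection,
metal streaks from a spinal screw, a stent's hyperintense ring).
Rasterization is by voxel centre with no anti-aliasing, so the true
vessel and calcium masks — and hence the true calcium volume — are exact
closed forms, independent of rendering, noise, or artifacts. Gaussian
noise is added last and truncated to [0, 255].

Default intensities (8-bit): background 35, wall 95, lumen 130,
calcification 195–230, bone 175–220. These were chosen once from the
physics of the protocol: the lumen must sit *below* the 145 scoring
threshold (contrast blood must never score), calcification strictly
above it, and the bone range must overlap the calcification range — that
overlap is precisely the confounding the segmentation model exists to
resolve. The generator validates these relations and rejects geometry
violations (vessel leaving the frame, arcs thicker than the wall, bones
intersecting the vessel). Noise σ = 4 gives >8σ separation between the
lumen and the threshold, so noisy phantoms stay scoreable; the spacing
default of 1 mm isotropic is a convention, as scanner spacing varies.

What the phantoms do *not* emulate: reconstruction physics (no Radon
transform or beam hardening — artifacts are phenomenological), soft-tissue
texture, branching vasculature, or sub-patellar small vessels. Passing
phantom tests therefore demonstrates that the measurement chain is
correct and that the model can learn shape-plus-intensity discrimination
under confounders and noise; it does not certify clinical performance on
patient CTAs, which the original protocol's reported accuracies address
and which require data this package cannot ship.

## Study conditions at desk scale

The package's own acceptance experiments, run by the test suite and by
`scripts/acceptance.R`, use these problem sizes, chosen once as the
smallest sizes at which every stage is exercised meaningfully:

* exactness checks: 20 noise-free 48×48×6 phantoms scored with
  ground-truth masks — recovery must be bit-exact against the closed
  form and an independent double-loop threshold oracle;
* metric checks: 200 random 16×16 mask pairs against a voxel-enumeration
  oracle; the identity `dice = 2·iou/(1+iou)` to 1e-12;
* learning check: 64×64 phantoms, 10 slices per patient, noise σ = 4;
  40 training slices (4 patients) plus one validation patient; width-8
  model, 30 epochs, batch 8, augmentation ×3, validation-based restart
  below best validation IOU 0.8; held-out mean per-slice Dice must reach
  0.8 on 8 unseen phantoms. The experiment is a fixed-seed protocol
  (cohort seed 42, initialization seed 42, held-out cohort seed 777),
  run single-threaded so the result does not depend on core count;
* end-to-end check: the same 8 held-out noisy phantoms scored with the
  trained model's predicted masks must track truth with MAPE ≤ 15% and
  least-squares R² ≥ 0.9 — the desk-scale analogue of
  automated-vs-manual score agreement.

## Numerical choices

* Per-patient segmentation accuracy is the mean of per-slice Dice
  scores, never pooled-voxel Dice; `slice_overlap_table()` is the single
  implementation of that contract.
* Both masks empty on a slice: Dice and IOU are 1 (perfect agreement on
  absence), and the per-slice table flags the slice. Annotated clinical
  slices always contain vessel, so the convention only matters for
  synthetic or cropped data.
* The APE/MAPE reference value must be strictly positive; zero
  references raise an error rather than returning infinity. Applying the
  APE definition to the reference score pair (7892 manual, 7707
  automated) gives 2.344%; a figure of 2.04% is sometimes quoted for
  this pair but does not follow from the definition, and this package
  follows the definition.
* BCE probabilities are clamped at ε = 1e-7; batch-norm uses ε = 1e-5
  and momentum 0.1 on running statistics.
* HU→8-bit rounding is round-half-up, pinned for bit-exact
  cross-implementation behaviour.
* Binarization of the probability map uses 0.5, exposed as a flag, since
  the protocol never states how probabilities become the {0,1} mask.
* Arrays are (row, col, slice), 1-based, with inclusive slice ranges —
  the native R convention, stated here once and used everywhere.
* All stochastic components (phantom sampling, noise, augmentation,
  initialization, shuffling) consume explicit seeds and restore the
  caller's RNG stream, so generators are pure functions of their seed.

## Known limitations

The convolution stack is a compact im2col+GEMM implementation sized for
desk-scale images; it is single-threaded per batch and not intended for
512×512 training at clinical throughput. The DICOM series reader is out
of scope (NIfTI and PNG stacks are supported); true Agatston scoring
with HU density weighting and bone subtraction are likewise out of
scope. The phantom cohort model draws each patient independently — there
is no scanner- or site-level variation structure.
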