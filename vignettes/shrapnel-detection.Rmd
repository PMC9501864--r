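---
title: "Detecting shrapnel near neurovascular structures: model, evaluation and triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shrapnel near neurovascular structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrapod)
```

## The problem

Retained shrapnel after penetrating trauma is common, and most fragments can
be managed conservatively. What makes a fragment urgent is not its presence
but its proximity to the neurovascular bundle — the co-located vein, artery
and nerve. Ultrasound is the natural bedside tool for this question, but
interpreting speckle-dominated images requires expertise that is scarce in
austere and military settings. `shrapod` implements a complete, testable
pipeline for this task: a synthetic ultrasound-phantom image generator, a
single-stage object detector for four classes (shrapnel, vein, artery,
nerve), the IoU-gated evaluation protocol, and a triage metric that converts
detections into a proximity-based flag.

## The synthetic phantom generator

Real ultrasound frames of gelatin thigh phantoms are not redistributable,
so the package generates its own annotated images. The generator emulates
the imaging setup of a two-layer gelatin phantom imaged transversely
(out-of-plane), so vessels appear as cross-sections:

* a speckled fat layer over a muscle layer, separated by a bright
  interface, with a bright bone arc and acoustic shadow at depth and a few
  soft echogenic patches mimicking heterogeneous muscle;
* an anechoic circular **artery** (8 mm lumen) with a bright wall;
* a darker compressed-oval **vein** (6.5 mm minor axis, wider than tall);
* a hypoechoic stippled **nerve** bundle (6.5 mm) lateral to the artery;
* with configurable probability, a bright **shrapnel** rod (2.5 mm
  diameter, 2–10 mm long, random orientation), re-placed until it does not
  touch the vein, artery or nerve, mirroring how fragments were inserted
  into the physical phantom.

Speckle is modelled as multiplicative Rayleigh noise (unit mean, 3×3
spatial correlation) on per-tissue mean echogenicities, followed by mild
depth attenuation and logarithmic amplitude compression. This reproduces
the *appearance statistics* that matter to a detector — granular
multiplicative texture, anechoic lumens, bright metal — not the physics of
wave propagation; there is no beam model, no reverberation or mirror
artifacts, and shrapnel comet-tail shadowing is off by default. Passing
tests on these images therefore demonstrates that the pipeline's
machinery works end to end, not that the trained weights would transfer to
clinical images.

The pixel scale is a free parameter because probe depth settings are
unknowable here. The default is 9.4 px/mm at 512 px (scaled proportionally
at other image sizes), chosen so the artery ground-truth box averages
about 75 px, which is also the reference length the triage gate is
expressed against. Ground-truth boxes are the tightest axis-aligned
rectangles around each rendered feature mask, in 0-based top-left pixel
coordinates.

```{r phantom}
img <- generate_phantom(phantom_config(image_size = 128), seed = 7)
img$boxes
```

## Augmentation

Training-time augmentation applies an independent random horizontal flip,
vertical flip, uniform scale in [0.8, 1.2] and rotation in [−360°, 360°]
to the raster, and maps each bounding box through the same affine
transform by mapping its four corners and taking the enclosing
axis-aligned rectangle (the standard detection convention), then clipping
to the frame. A draw under which any box exits the frame entirely is
rejected and redrawn, so augmentation conserves per-class box counts.
Validation and test images are never augmented.

## The detector

The network is a SqueezeNet-style backbone with two YOLO-style output
heads. A stem convolution (3×3, stride 2, ReLU, max pool) is followed by
four shared Fire blocks and five more on the class-path; each Fire block
squeezes with a 1×1 convolution and expands through parallel 1×1 and 3×3
convolutions concatenated in depth. The fine head reads the last Fire
concatenation at stride 16 through a conv + batch-norm + ReLU block; the
coarse head (stride 32) fuses a stride-2 feature-resizing conv block on
that concatenation with the pooled second-to-last Fire block, followed by
a final concatenation and conv block. Each head ends in a linear 1×1
convolution emitting `anchors × (5 + classes)` channels: sigmoid x/y
offsets within the grid cell, log-scale width/height against the anchor,
objectness, and per-class scores.

Channel widths follow SqueezeNet v1.1 scaled by a width multiplier; the
exact widths and the stride-16/32 split are design choices, since only the
block topology is fixed by the architecture description. Anchors are
estimated from training boxes by k-means under the `1 − IoU` shape
distance (23 by default, which suits the full-scale setting; the
CPU-scale profile uses 6), sorted by area and split between the heads,
larger shapes to the coarser head.

Training uses SGD with momentum 0.9, batch size 16, L2 regularization
5e-4, and a learning rate that warms up over 1000 iterations as
`0.001 × (iteration / 1000)^4`, then stays constant. The quartic
expression could also be read as a post-warmup slowdown; both readings are
implemented (`post_warmup = "decay"` gives the mirrored
`0.001 × (1000 / iteration)^4`), with ramp-up-then-constant as the
default because that is how the expression is used in the reference
detector implementations this recipe descends from. The loss is the
standard single-stage composition: squared error on the assigned
predictors' box offsets (each ground truth is assigned to the anchor whose
shape matches it best), weighted by `2 − box area / image area` so that
small objects such as shrapnel fragments are not dominated by the large
vessel boxes, plus binary cross-entropy on objectness and on class
scores. Predictors that are not assigned but whose
decoded box overlaps any ground truth at IoU ≥ 0.5 (the penalty
threshold) are excused from the no-object penalty. All backpropagation is
implemented in the package (im2col-based convolutions in C++, exact
gradients verified against numerical differentiation in the test suite).

Inference decodes both heads, scores each candidate as objectness × best
class score, keeps candidates above a 0.5 confidence threshold (a
convention, as is the 0.5 per-class NMS IoU; neither is prescribed) and
applies per-class non-maximum suppression.

## Evaluation protocol

Detections are matched greedily per image and class in descending
confidence order: a detection is a true positive when it claims an
unmatched ground truth at IoU ≥ 0.5; every other detection — including a
surplus detection on an already-claimed ground truth — is a false
positive, and unmatched ground truths are false negatives. The per-image
IoU sample for the mean-IoU (mIoU) distribution is the mean over ground
truths of their matched IoU, with 0 recorded when no detection claimed a
present ground truth and for detection-only images; images with neither
detections nor ground truth for a class contribute no sample. Average
precision is the area under the pooled precision–recall curve with the
all-point precision-envelope interpolation (a raw trapezoid option is
available). Per-class rows report %TP/%FP/%FN as percentages of
TP+FP+FN, precision, recall, F1, mIoU and AP; the all-class average row is
the unweighted mean of each column, with undefined (0/0) ratios reported
as missing and excluded from averages.

## Triage metric

For each image whose detections include all four classes, the single
highest-confidence detection per class is selected (ties broken toward the
larger box). The box midpoint is `(x + w/2, y + h/2)`; the three Euclidean
midpoint distances from shrapnel to vein, artery and nerve are computed in
pixels, and the minimum is the triage distance, attributed to the closest
feature (ties broken artery, then nerve, then vein — most critical
first). An image is flagged at gate multiplier `m` when its triage
distance is strictly below `m ×` the reference diameter, the mean over
artery ground-truth boxes of `(w + h)/2` (~75 px at the default scale).
The flagged fraction is nondecreasing in the multiplier by construction.
Distances stay in float pixels; an optional calibration factor converts to
millimetres when a reference length is known.

## Numerical choices and degenerate inputs

* IoU of two zero-area boxes is an error, not 0; zero-area boxes produced
  by clipping are dropped.
* Exact IoU ties in matching go to the lowest-index ground truth;
  confidence ties in triage selection go to the larger box, then first
  seen.
* Anchor k-means stops as soon as an update would increase the mean
  `1 − IoU` objective, so the objective is nonincreasing; empty requests
  (k beyond the number of distinct shapes) are errors.
* Splitting uses largest-remainder rounding of the 75/10/15 fractions and
  keeps every part non-empty; fewer than three images is an error.
* All randomness flows through seeded Mersenne-Twister streams that are
  restored after use; fixed seeds make generation, training and the full
  pipeline bit-reproducible.
* Batch norm uses batch statistics during training and running averages
  (momentum 0.1) at inference.

## The CPU-scale profile

The published training recipe (512×512 inputs, ~8000 images, 125 epochs)
is far beyond a single-CPU R session. The package's default test and
pipeline profile therefore uses 128×128 images (2.35 px/mm, preserving
the anatomy's relative proportions), a width-0.25 network (~180k
parameters), 6 anchors, batch 8, a 100-iteration warmup, a 1000-iteration
main schedule and a 300-iteration fine-tuning phase at learning rate 1e-4 —
enough for the detector to memorize a 10-image set to perfect AP and to
generalize usefully on held-out synthetic images. Several deliberate
departures from a miniature copy of the full recipe, all made as profile
design choices:

* **Augmentation is disabled in the CPU-scale pipeline profile.** With
  ±360° rotations the effective task (recognize the anatomy at any
  orientation) needs far more data and iterations than the profile's
  budget; a probe run at this scale with full augmentation plateaus near
  chance. Augmentation itself is fully implemented, tested, and on by
  default in `train_config()` for full-scale use.
* **Iteration count replaces epoch count** (`max_iters`), since at this
  scale epochs are only a few iterations.
* **Validation-based checkpoint selection.** The validation split is
  scored every `val_frequency` iterations and the lowest-validation-loss
  parameters are restored at the end of the run (`keep_best`); constant-lr
  SGD at this scale oscillates, and the selection removes most of the
  run-to-run noise.
* **A low-learning-rate fine-tuning tail** (300 iterations at 1e-4)
  stabilizes box regression after the main schedule; the paper-scale
  recipe trains long enough not to need one.

At this resolution a shrapnel rod is only about six pixels wide, and its
tight box rarely clears the IoU 0.5 bar, so the profile's shrapnel AP is
far below the vessel APs; at the full 512 px scale the same code sees
four times the detail. This is a resolution limitation of the profile,
not of the method.

These are the problem sizes the acceptance computation also uses; the
vignette's numbers and the README's worked example come from exactly these
settings.

## Known limitations

* The generator renders one neurovascular bundle and at most one fragment
  per image; the paper's phantoms also varied probe positioning across
  quarters, which is only weakly emulated by randomized feature placement.
* Synthetic speckle is spatially stationary; real muscle anisotropy,
  probe-pressure deformation and shadowing artifacts are absent, so
  detection scores on synthetic data say nothing quantitative about
  clinical performance.
* The triage metric is midpoint-based; for large or irregular features a
  corner-to-corner or segmentation-based distance would represent
  proximity better.
* Closest-feature frequencies are forced to sum to 100% of scored records
  (deterministic tie-breaking); published tables based on manual review
  may not.
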