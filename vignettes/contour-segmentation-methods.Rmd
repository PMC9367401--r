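---
title: "Methods: contour-based instance segmentation with a few-shot detector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contour-based instance segmentation with a few-shot detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(contourseg)
```

## The problem

Camera traps produce large volumes of wildlife imagery in which animals must
be located, identified to species, and outlined. Pixel-based instance
segmentation needs dense per-pixel supervision and large training sets —
both scarce for rare species. `contourseg` implements the alternative this
package is built around: a **two-stage contour-based pipeline**.

1. A **few-shot object detector** (backbone → region proposal network →
   ROI pooling → fully connected layer → box classifier + box regressor)
   finds species boxes. It is trained in two stages: *base training* on
   abundant classes updates everything; *fine-tuning* on an n-shot subset
   (n images per class, base and novel) updates only the box predictor,
   with the feature extractor frozen. Novel species therefore become
   detectable from a handful of images.
2. A **learning-based active contour ("deep snake")** turns each box into
   an instance outline: the box's edge midpoints form a diamond contour; a
   circular-convolution network predicts the four extreme points (top-,
   left-, bottom-, right-most object points); an octagon is built from the
   extremes by extending a quarter of the corresponding box edge each way,
   clipped at the box corners; the octagon, resampled to N vertices, is
   deformed by per-vertex offset regression for a fixed number of
   iterations.

Everything runs at desk scale on one CPU against a synthetic scene
generator with exact ground truth, so the full pipeline is testable
end-to-end without any external download.

## Models and parameters

### Contour representation

A contour is an ordered cyclic list of 2-D points, clockwise in image
coordinates, without a duplicated endpoint. Coordinates are continuous with
the origin at the top-left image corner and pixel centers at half-integers;
boxes are half-open, which makes rasterization and IoU unambiguous
(`contour_to_mask()` marks pixels whose centers fall inside the polygon,
even-odd rule). `resample_contour()` places vertices at equal arc length
starting from the first vertex — no phase optimization, so results are
deterministic. Uniform spacing preserves original vertices only when the
spacing divides the edge lengths (true for the diamond, whose four sides
are equal); otherwise corners are cut by an amount that vanishes with
density.

### Snake configuration (`snake_config()`)

| parameter | default | meaning |
|---|---|---|
| `n_diamond` | 40 | points sampled on the diamond; the 36 non-midpoint points supply context, offsets are read only at the 4 original midpoints |
| `n_contour` (N) | 128 | points sampled on the octagon; N offsets are output per deformation round |
| `iterations` | 3 | deformation rounds; one round cannot regress large moves, iterating splits them |
| `kernel_size` | 3 | circular-convolution width (odd; cyclic wrap, no boundary) |
| `feature_dim` | 48 | appearance channels: 16 stride-2 + 32 stride-4 pyramid levels |
| `hidden_dim` | 64 | width of the snake-block circular convolutions |

A **snake block** is two circular-convolution layers with ReLU, a fused
global feature (channel-wise max over vertices, broadcast back — this
pooling is cyclic-shift invariant, so the whole block is equivariant to
cyclic relabeling of the vertices (exactly in real arithmetic; to within
BLAS reduction order, about 1e-15, in floating point)), and a per-vertex linear
head producing 2-D offsets. Per-vertex input features are bilinear samples
of a two-level convolutional feature pyramid at the vertex position,
concatenated with centroid-relative coordinates normalized by their RMS
radius. The normalization keeps the geometric channels O(1) for any object
size; the two pyramid levels trade off localization (stride 2) against
context (stride 4).

Several components are deliberate design choices where the lineage of
contour-deformation networks leaves them open: smooth-L1 (Huber, delta 1)
losses; ground-truth/prediction vertex correspondence by nearest-start
alignment then cyclic index order; no re-resampling between iterations
(offsets accumulate on the same N vertices); the contour is detached
between iterations, so each round is supervised as its own regression and
no gradient flows through sampling coordinates. Predicted extreme points
may drift off the box edge; they are projected onto their corresponding
edge before octagon construction, because the quarter-edge rule is only
defined on the box boundary.

### Detector (`detector_config()`, `train_config()`)

The detector keeps the canonical two-stage structure at reduced scale: a
6-layer strided convolutional backbone (stride 4, 24 output channels)
stands in for a deep residual backbone; a single-scale RPN scores 9 anchors
per location (scales 16/32/64 px, aspect ratios 0.5/1/2); ROI features are
3×3 bilinear samples; one FC layer (96 units) feeds the box predictor. The
box regressor is class-agnostic (one 4-vector per ROI). The FC layer
belongs to the frozen feature extractor — fine-tuning touches only the
classifier and regressor heads, and novel-class classifier rows are
initialized from a zero-mean Gaussian (sd 0.01).

Training follows the standard recipe: SGD, batch size 2, momentum 0.9,
weight decay 1e-4, learning rate 0.02 for base training and 0.001 for
fine-tuning. Epoch counts are not part of the recipe and are exposed as
configuration (defaults: 6 base epochs, 40 fine-tuning epochs — the latter
are cheap because frozen-extractor ROI features are cached once per subset
image). A global gradient-norm clip (5) guards the high base learning rate
on small batches; it is a numerical safeguard, not a tuning knob.
Categories split 3:1 into base and novel classes (9 + 3 for 12 classes),
deterministic given the seed.

## The synthetic scene generator

`generate_dataset()` emulates the structure of a balanced camera-trap
dataset: 12 shape classes, 40 images per class by default, 128×128 RGB,
stratified 0.85 train/validation split, roughly 1.4 instances per image
(single species per image, as in typical camera-trap frames). Each class
is a truncated Fourier radial series `r(θ) = s(1 + a_m cos(mθ + φ) + …)`
with a class-specific dominant order (2–5) and amplitude tier, a distinct
base color, a mild random aspect stretch and rotation. Radial curves with
r > 0 are simple by construction, and the dense boundary gives exact
extreme points, areas and boxes — the generator is the pipeline's ground
truth, not an approximation.

Four challenge regimes mirror the hard cases of field imagery, each drawn
independently per scene with probability 0.15: **small targets** (radius
7–11 px, several instances), **overlap** (a second instance placed at
60–90 % of the combined radius, composited in front), **camouflage** (body
color sampled from the background color with a small offset, so boundaries
are texture-limited), **truncation** (instance centered near the border;
polygon and box clipped to the frame). Occlusion is recorded as a
rasterized `visible_area` per annotation; the annotation polygon itself is
the instance outline clipped to the frame, so contour supervision always
has a single closed curve (multi-component masks are out of scope).

What passing tests on this generator do *not* show: robustness to
photographic texture, lighting, motion blur, or deformable articulated
silhouettes. The generator's separability is verified explicitly (a
nearest-centroid classifier on rotation-invariant radial signatures must
exceed 90 %), so a failure to learn would indicate a pipeline defect, not
an impossible task.

## Numerical choices

- Rasterization uses the even-odd rule on pixel centers; self-intersecting
  contours rasterize without error (deformation can transiently
  self-intersect).
- `build_octagon()` accepts extreme points up to `tol` outside the box
  (default half the box half-perimeter) and projects them; beyond that it
  raises an invalid-geometry error, since a far-outside extreme indicates
  an upstream failure.
- NMS breaks score ties by original index; detections are sorted
  score-descending, so evaluation is deterministic.
- Box-delta decoding clamps deltas at ±4 before exponentiation.
- Degenerate inputs error early with typed messages (`parameter:`,
  `invalid-geometry:`, `data:`, `state:`, `contract:`).
- Training determinism: every stochastic step (init, shuffling, sampling,
  jitter) derives from the run seed; two runs with the same seed produce
  loss curves equal to floating-point reduction order.

## Problem sizes used in tests and the acceptance script

The package's own studies run at the generator's default scale: 12 classes
× 40 images at 128×128 (408 training, 72 validation images). Snake
training uses 10 epochs with a step learning-rate decay (×0.1 for the final
third), about 4 CPU-minutes; detector base training uses 6 epochs on the
9 base classes. The n-shot study fine-tunes at 1, 2, 3, 5, 10 and 30 shots.
Base training is performed once and three fine-tuning seeds vary the
novel-row initialization, the subset draw and SGD sampling: the shot-level
comparison varies only the fine-tuning stage, so sharing the frozen
extractor across seeds is exactly the two-stage contract and keeps the
comparison clean. Unit tests use miniature datasets (4–6 classes, 6–12
images per class) generated in code.

## Known limitations

- One contour per instance: holed or disconnected masks cannot be
  represented.
- The contour is supervised point-to-point after nearest-start alignment;
  the tangential component of that correspondence is noisy, which bounds
  the achievable loss but barely affects region overlap.
- The desk-scale detector saturates well below what a deep backbone
  reaches on real imagery; its purpose is to preserve the structural
  contract (frozen extractor vs tuned predictor) and the qualitative
  n-shot trend, not absolute accuracy.
- Static images only; no video tracking.

## Worked example

```{r example}
library(contourseg)

ds <- generate_dataset(n_classes = 6, images_per_class = 10, seed = 1)
snake <- train_snake(ds, seed = 1)
ev <- evaluate_snake(snake, ds, split = "val")
aggregate(iou ~ iteration, ev, mean)

split <- split_base_novel(ds$categories, seed = 1)
base_ids <- which(vapply(ds$images, function(im)
  im$split == "train" && im$class_id %in% split$base_classes, logical(1)))
```

The README shows the full pipeline run with the numbers it prints.
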