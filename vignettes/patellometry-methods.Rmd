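---
title: "Methods: landmark regression and patellofemoral morphometry"
author: "patellometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark regression and patellofemoral morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the measurement
definitions, the preprocessing chain, the two-stage landmark model, the
synthetic phantom that stands in for clinical CT, and the numerical and
design choices behind each. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinates, units, conventions

One convention is used everywhere: coordinates are 0-based, `x` indexes
columns, `y` indexes rows, and pixel centers sit at integer coordinates;
an image is an R matrix addressed as `m[y + 1, x + 1]`. Physical scale
lives only in the series metadata (`pixel_spacing`, cm per pixel), never
baked into coordinates; all distances are computed in original-resolution
pixel space and scaled once. Angles are dimensionless, so every derived
measurement is invariant under rigid in-plane rotation, translation and
mirroring of the landmark scene — a property the acceptance suite checks
directly.

## The four patellofemoral parameters

Seven landmarks per axial slice: `A` trochlear central trough, `B`/`C`
trochlear medial/lateral aspects, `D`/`E` medial/lateral peripheral
epicondyles, `F`/`G` medial/lateral posterior condyles.

- **TEA length.** Per slice, the transepicondylar length is the Euclidean
  distance between the most medial and most lateral of the seven
  landmarks (extremes along `x` in canonical orientation; in practice `D`
  and `E`). The slice with the longest span defines the TEA — the
  directed line through those two extremes — and its length in cm. Ties
  break toward the lowest slice index; the extreme landmark names are
  logged in the result.
- **TEA–PFA angle.** The posterior femur axis is the line `F`–`G`; the
  reported angle is the acute angle between TEA and PFA directions, in
  `[0, 90]` degrees, unsigned.
- **Trough slice.** Per slice, the perpendicular distance from `A` to the
  TEA line; the slice minimizing it is selected (ties to the lowest
  index).
- **Asymmetry ratio.** `A`, `B`, `C` are orthogonally projected onto the
  TEA; the ratio is G–L / M–L, i.e. |proj C − proj A| over
  |proj C − proj B|. We adopt the G–L / M–L orientation because a near
  centered groove should read ≈ 0.5 on this scale; the ratio is 0 when
  the trough projects onto the lateral aspect and 1 at the medial aspect,
  and is monotone in between.
- **Sulcus angle.** The angle at vertex `A` between the rays to `B` and
  `C`, in `(0, 180]` degrees; 180 is a flat groove.

Numerical choices: both angles are computed as `atan2(|cross|, dot)`
(folded with `|dot|` for the acute TEA–PFA angle) rather than
`acos(dot / |u||v|)`. The `acos` form loses up to half its significant
digits near parallel or antiparallel configurations; the `atan2` form is
well-conditioned everywhere and agrees with independent oracles to 1e-9
relative error in the acceptance suite. Degenerate geometry (coincident
points defining a line, zero M–L projection) raises an error naming the
offending landmarks rather than returning a value.

Mirroring: `mirror_series()` reflects images and x-coordinates and toggles
laterality. Landmark labels follow the anatomy and are *not* relabelled —
the mirrored right knee *is* the corresponding left knee, whose medial
epicondyle legitimately sits at larger `x`. Relabelling medial/lateral
landmarks would silently replace the asymmetry ratio r by 1 − r; keeping
labels attached to anatomical points makes all four measurements exactly
mirror-invariant.

## Preprocessing

The chain reproduces a standard CT bone-windowing front end:

| parameter | default | unit | role |
|---|---|---|---|
| `window_level` | 350 | HU | window center |
| `window_width` | 2000 | HU | window breadth; maps [−650, 1350] → [0, 255] |
| `sigma` | 2 | px | Gaussian smoothing before bone thresholding |
| `threshold` | 105 | 0–255 | bone threshold on the windowed image |
| `out_size` | 160 | px | model image side |
| `patch_size` | 36 | px | refinement patch side |
| `max_shift` | 10 | px | train-time patch-center shift augmentation |

Windowed intensities are kept as floats (no integer quantization) to avoid
double rounding before model input. The bone bounding box is the tight box
of the largest connected component above threshold on the smoothed
windowed image — the threshold is defined on the 0–255 windowed scale, not
raw HU (105 is only meaningful there). `sigma = 2` px is small enough not
to merge the femur with noise blobs at 512×512 but suppresses
single-pixel noise; it is exposed in the configuration. An image with no
supra-threshold pixel is an error ("no bone found"), not an empty box.

The crop is padded symmetrically to a square before bilinear resampling to
160×160 (`resize_mode = "pad"`). Aspect-preserving resampling is the
default because anisotropic stretch would distort the angles the
downstream morphometry depends on; `"stretch"` reproduces the naive
non-square resize for comparison. The `crop_transform` records the exact
affine map; `map_coords()` applies it forward (annotations into model
space) or inverse (predictions back to original resolution, where all
evaluation happens). The map is corner-aligned (bbox corner → origin,
pure scaling); the bilinear resampler aligns pixel centers, a fixed
sub-half-pixel convention difference far below annotation precision. The
round trip is exact to floating point (< 1e-6 px over random boxes in the
acceptance suite).

Patch samples: integer shifts drawn uniformly from [−10, 10]² (the
augmentation is specified only as "up to 10 pixels"; the uniform-integer
reading is the least informative choice), window clamped to image bounds
with the effective origin recorded, target = landmark in patch
coordinates. At inference the patch is centered on the aligner estimate
with no shift. Targets are regressed as absolute patch coordinates
normalized by the patch size, keeping MSE magnitudes comparable between
the 160-px aligner frame and the 36-px patch frame.

## The two-stage landmark model

Both stages share one backbone family: a stem 3×3 convolution (stride 2)
followed by residual stages, each a stride-2 entry convolution plus an
identity residual block. The terminal activation of every stage is
globally average-pooled and concatenated into the flattened feature
vector feeding the linear regression head — the multi-stage supervision
mechanism, which lets features from every depth reach the head directly.
"Connecting each residual block's last layer to the final flattened
layer" is under-specified as an architecture; global-average-pool +
concatenation is our interpretation, chosen because it preserves the
per-stage features at any input size with a fixed head width.

The default (`depth = "small"`) backbone has stem width 8 and stage
widths 8/16/32/64 — deliberately small so the full pipeline trains on one
CPU in minutes; `depth = "deep"` widens and adds a stage with the same
topology. The aligner regresses 14 outputs (7 landmarks × 2 coordinates,
normalized by 160); each of the 7 patch models regresses 2 (normalized by
36). The forward/backward passes are hand-written in RcppArmadillo
(im2col convolutions); analytic gradients match finite differences to
1e-6 in the tests, which is the package's substitute for autograd
correctness.

Training: MSE loss, Adam (β₁ = 0.9, β₂ = 0.999), learning rate from
{0.001, 0.0005, 0.0001} with ×0.95 decay per epoch. Epoch count and batch
size are not externally prescribed; the desk-scale defaults are 20 epochs
and batch 32. Initialization is He-normal for convolutions; the head has
a small-variance weight matrix and bias 0.5 so untrained predictions sit
at the image center. Fixed seeds make runs bit-reproducible on the same
machine (weight init, batch order and patch shifts all derive from the
configured seeds). A non-finite loss aborts with a diagnostic. The
best-vs-last checkpoint question is resolved as last-epoch: with a
monotone decaying schedule on stationary synthetic data the final epoch
is the natural choice and keeps checkpoints deterministic.

Inference composes the stages: aligner point → 36×36 patch centered on it
(clamped to bounds) → patch model's coordinate inside the patch → lifted
through the patch origin and the inverse crop transform. A refined point
can therefore never leave the patch footprint (36·√2 px in model space),
which bounds the damage a bad patch model can do. If the clamped patch no
longer contains the aligner point (an off-image coarse prediction), the
aligner point is kept and the slice flagged — refinement never
extrapolates.

### Contrastive pretraining

`simclr_pretrain()` trains the backbone on unlabeled preprocessed slices:
two stochastic augmentations per image (random crop-resize with area
scale in [0.6, 1], horizontal flip, brightness jitter ±0.2 — a menu and
temperature of 0.1 chosen as conventional defaults, all configurable),
a 2-layer projection head, and the NT-Xent loss. One adaptation was
needed: without normalization layers, the pooled features of a randomly
initialized backbone are dominated by a shared offset, all cosine
similarities start near 1, and the NT-Xent gradient vanishes (it is
projected out by the embedding normalization). The projection head
therefore standardizes features over the batch first; centering is
backpropagated exactly, the scale statistic is treated as a constant in
the backward pass. Pretrained weights seed `train_regressor` via
`init`; the regression head is re-initialized. An externally trained
weight file can be supplied through the same `init` hook; none ships with
the package.

## The synthetic phantom

The phantom emulates what the pipeline needs from axial knee CT and
nothing more: 512×512 slices at 0.04 cm/px; a bicondylar cross-section
built from two overlapping filled ellipses (the simplest shape family
with independently controllable width, posterior tilt and groove
geometry); a wedge-shaped groove cut between B–A–C whose walls are
straight lines, so the sulcus angle is exact by construction; bone at
700 HU on 40 HU soft tissue (windowing to 172 vs 88, comfortably
straddling the 105 bone threshold) with additive Gaussian noise of
50 HU; 9 slices per knee with quadratic slice-to-slice profiles of
condylar width and trough depth, so the TEA slice and the trough slice
are unique interior slices by construction (no ties). Landmarks are
stored in continuous sub-pixel coordinates; the rendered mask is their
discretized shadow, so ground truth does not inherit rasterization
error — parameter recovery from ground-truth landmarks is exact to
~1e-12, well inside the ≤ 1 px propagated tolerance the recovery grid
asserts. Knee position, condylar height and groove width jitter per
series; the trough-depth profile amplitude adapts to the available
margin so every groove stays strictly below the aspects.

What the phantom does **not** emulate: cortical/trabecular texture, the
patella and soft tissue, osteophytes and subchondral sclerosis of
osteoarthritic knees, partial-volume effects, scanner-specific noise
spectra, and oblique slice orientations. Passing tests on phantoms
therefore demonstrate that the pipeline's machinery is correct and that
the two-stage design refines the coarse stage under controlled
conditions; they do not certify clinical accuracy on real CT, which
requires the original annotated cohorts.

## Problem sizes in the tests

The acceptance suite trains on 34 phantom knees (306 slices), evaluates
on 6 held-out knees (54 slices, 378 landmark points), runs the recovery
grid over 60 parameter combinations spanning sulcus 110–160°, ratio
0.3–0.7, TEA 7–9 cm, TEA–PFA 0–10°, and pretrains on 207 slices for 5
epochs — sizes chosen so the whole suite completes in a few minutes on a
single CPU while keeping every comparison statistically unambiguous
(the stage comparison is a paired t-test over 378 per-point distances).

## Known limitations

- The landmark model is 2-D per slice; no 3-D context or oblique-plane
  axis fitting.
- `read_series()` supports NIfTI volumes with JSON sidecars; DICOM series
  must be converted upstream.
- The independent t-test defaults to Welch; the pooled form is available
  by flag. Bland–Altman limits use the sample standard deviation.
- Measurement extremes ("most medial/lateral") are x-extremes in
  canonical orientation; extreme rotations of a whole scene (beyond what
  positioning produces, ≳ 30°) could change which landmarks are extreme.
- The reduced-depth backbone is sized for desk-scale training; clinical
  deployment would use the deep variant, longer schedules and real
  annotated CT.
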