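---
title: "Methods: joint segmentation and quantification of the left ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint segmentation and quantification of the left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical assessment of left-ventricular (LV) function from short-axis cine
MRI rests on a small set of per-frame indices: the cavity and myocardium
areas, three cavity diameters measured along fixed anatomical directions
(IS-AL, I-A, IL-AS), six regional wall thicknesses (RWT; segments IS, I,
IL, AL, A, AS), and the binary cardiac phase (systole/diastole). `lvquant`
implements a task-unified estimator of all eleven indices plus the phase:
a 3D hybrid CNN–Transformer network segments the cavity, myocardium and
background in a 5-frame temporal window, while a spatio-temporal
convolutional regression network — fed both the raw window and multi-scale
decoder features of the segmentation path — predicts the indices and phase
of the window's centre frame. Both paths are trained jointly with a
weighted multi-task loss.

Alongside the networks, the package provides the two deterministic tools
needed to build and validate such an estimator without access to a
clinical dataset: a parametric beating-LV phantom with analytically exact
ground truth, and a centroid ray-casting morphometry module (the
"Calculation" baseline) that measures the same indices directly from label
masks.

## Conventions

Masks are `H x W` integer matrices over {0 background, 1 cavity,
2 myocardium}; pixel centres sit at integer 0-based (row, col)
coordinates. Angle 0 points image-right and angles increase
counter-clockwise; the anterior segment bisector points up (90°) and the
remaining bisectors follow every 60°, so the segment order IS, I, IL, AL,
A, AS corresponds to 210°, 270°, 330°, 30°, 90°, 150°. Short-axis
challenge images are pre-rotated into a canonical pose, so these are fixed
image directions; the anatomical names label them. Areas are normalized by
the pixel count `H*W`, lengths by the image height `H`; physical units are
recovered by `length * H * spacing` (mm) and `area * H * W * spacing^2`
(mm²), with the default spacing 1.5625 mm/pixel (the modal value of the
intended acquisitions).

## The phantom

The phantom is a continuous model of one mid-cavity slice over a 20-frame
cardiac cycle. The endocardial boundary is a circle of radius
`r_endo(t) = r_ed + (r_es - r_ed) c(t)` modulated by low-order angular
harmonics (orders 2–4, amplitudes ≤ 0.1); the raised-cosine contraction
profile `c(t)` rises from 0 at end-diastole (frame 0) to 1 at the
configured end-systolic frame and returns to 0, giving a smooth periodic
area curve with a single minimum. The epicardium adds a per-segment wall
thickness, interpolated piecewise-linearly in angle between the six
bisectors and thickening towards end-systole. Images assign class mean
grey levels (background 0.2, myocardium 0.45, cavity 0.8 — the blood pool
is bright on cine SSFP), multiply a low-frequency bias field, add Gaussian
noise and clip to [0, 1]. Masks classify each pixel centre against the
continuous radii — a hard 3-class field with no antialiasing, like
challenge ground truth.

Ground-truth indices are computed from the continuous model, never from
the rasterized mask: areas by polar quadrature of the boundary radii
(composite trapezoid on 2048 points per 60° sector, aligned to the
interpolation breakpoints), dimensions as paired endocardial radii,
RWT as the continuous wall at each bisector. `sample_phantom_spec()` draws
cohort-style variability: ED endocardial radii 12–20 px with ES/ED ratios
0.5–0.8 (dysfunction to normal ejection), ED wall 4–12 px (6–19 mm at the
modal spacing — normal to hypertrophic), systolic thickening 15–55%,
centre jitter, noise and bias. The `easy` mode draws concentric,
noiseless subjects with uniform walls from narrower ranges. All ranges
scale proportionally with `image_size`.

What the phantom does **not** emulate: papillary muscles and trabeculae,
through-plane motion, multi-slice (basal/apical) anatomy, coil shading
beyond a smooth bias, and MR acquisition physics. Tests passing on
phantoms therefore demonstrate the correctness of the pipeline's
machinery and its behaviour under idealised anatomy, not clinical-grade
accuracy.

## Ray-casting morphometry (the "Calculation" baseline)

From a mask, areas are normalized pixel counts per class. All length
measurements march a ray from the cavity centroid (mean of cavity pixel
centres) with a 0.1 px step, reading the class of the nearest pixel, and
localise each class change at the midpoint of the two straddling samples.
A cavity dimension is the distance between the two endocardial
(cavity→myocardium) crossings of the full line through the centroid along
the axis of its segment pair. An RWT is the distance between the
epicardial and endocardial crossings along the segment direction. A ray
that leaves the cavity directly into background signals a broken
myocardium ring as an error rather than a silent zero, so defective
segmentations surface.

One design choice deserves a note. A single ray per segment carries
roughly 0.4 px of noise from mask rasterization, which is irreducible by
step refinement; at 80 px resolution this caps the pooled RWT correlation
against the continuous truth just below the level the rest of the
pipeline achieves. `regional_wall_thickness()` therefore averages a
narrow symmetric fan of five rays at ±6°, ±3° and 0° around each
bisector. Over such a small arc the piecewise-linear wall model is linear,
so the fan estimates the same quantity while suppressing the rasterization
noise by roughly the square root of the ray count; `fan_deg = 0` restores
the strict single-ray reading.

The phase is derived from the cavity-area series: ED is the argmax, ES the
argmin, frames cyclically after ED up to and including ES are systole (1),
the rest diastole (0). A constant series has no phase and raises an error.

## Networks

Tensors use the layout `(H, W, slices, channels, batch)`. Both paths run
on a compact reverse-mode automatic-differentiation engine written for
this package: a dynamic tape over R arrays with RcppArmadillo im2col/GEMM
kernels for 3D convolution, transposed convolution and max pooling, and
vectorised R implementations of the normalisation, attention and
reduction operators. Every operator is finite-difference checked in the
test suite.

**Segmentation path.** A residual 3D-conv stem (kernel 3, group
normalisation, randomized leaky ReLU with slopes drawn from [1/8, 1/3] at
training time and fixed at the midpoint for evaluation) downsamples
spatially three times with 1×2×2 max pooling — the slice axis is never
pooled. A patch-embedding convolution of spatial stride 2 then produces
the token grid: for an 80×80, 5-slice window, 5×5×5 cells of `hidden`
channels, i.e. 125 tokens of width 256 in the default configuration
(three poolings take 80 to 10; the stride-2 embedding supplies the final
halving to the 5×5×5 grid). A pre-norm multi-head
self-attention encoder (depth 4, 8 heads, MLP ratio 4 by default; learned
positional embeddings) processes the tokens. The decoder reshapes tokens
back to the grid and cascades four 1×2×2 transposed convolutions,
concatenating the matching pre-pooling stem skip at each scale, ending in
a 1×1×1 convolution to 3-class logits for all five slices. Decoder
features at the full and half scales are exposed to the regression path.

**Regression path.** The raw window passes through a
recurrent-residual-attention (RRA) block — two recurrent-residual conv
units (the same kernel-3 convolution applied `recurrence` times, the unit
input re-injected each pass; batch norm + ReLU) followed by
squeeze-and-excitation channel attention — then through two
spatio-temporal blocks. Each spatio-temporal block applies an unpadded
3×1×1 temporal convolution (slices 5→3→1), a padded 1×3×3 spatial
convolution, batch norm, ReLU and 1×2×2 max pooling. The unpadded
temporal convolutions do the slice reduction (the 1×2×2 pooling touches
only the spatial axes), so the output describes the central slice: after
two blocks the single remaining slice has a symmetric temporal receptive
field covering all five input slices. Decoder features are fused at both scales by channel
concatenation, squeeze-and-excitation over the joint channels and a 1×1×1
projection; the half-scale decoder features contribute their central
three slices. Two heads read the collapsed map: a shallow convolutional
regressor (1×1×1 conv, global average pooling, linear) emitting the 11
indices, and a 360-unit perceptron emitting 2 phase logits. Index outputs
are unbounded (targets lie in [0, 1)); an optional sigmoid clamp is off by
default.

**Loss.** With per-pixel softmax probabilities `p` and one-hot targets
`y`, the segmentation loss is `λ1·CE + λ2·Dice` with CE the pixel-mean
cross-entropy and Dice the class-averaged soft overlap
`1 − (2/K) Σ_k (Σ y p) / (Σ (y + p))` (smoothing 1e-5 in numerator and
denominator), supervised on all five slices. The regression loss is the
MSE over the 11 indices (mean over samples and indices jointly, so the
scale is independent of the index count) plus the binary cross-entropy of
the phase probability. The unified objective is `λ3·L_seg + λ4·L_reg`
with defaults λ1=1, λ2=1.5, λ3=4, λ4=1 — the segmentation path is
weighted above the regression path because the latter feeds on its
features.

**Training.** The segmentation parameters update with rectified Adam
(lr 5e-4, β1 0.9, β2 0.999, weight decay 1e-4, exponential decay 0.99 per
epoch); the regression/classification parameters — including the fusion
layers, which exist only for regression — with SGD (lr 5e-4, weight decay
5e-3, momentum 0.06). Both optimizers step simultaneously on each batch
of 20 five-frame windows; gradients from the regression loss flow into
the segmentation path through the fused features (a stop-gradient switch
exists for ablation). Preprocessing applies CLAHE per frame (clip limit
2, 8×8 tiles) and z-score normalisation per subject stack, identically at
training and evaluation time so the input distributions match. Training-time augmentation — a shared rotation
in ±90°, flips with probability 1/2, a smooth elastic field
(control-point spacing 16 px, σ 2 px), and an image-only gamma shift in
[0.5, 1.5] — is available but off by default for phantom experiments,
where rotations would desynchronise the segment-resolved targets from the
images. Cross-validation partitions subjects (never frames) into folds of
near-equal size. After a training run the batch-norm running moments are
re-estimated under the final weights (forward passes with update weight
1/k), so short desk-scale runs evaluate consistently.

## Desk-scale configurations and problem sizes

The package's tests and the acceptance script run everything on one CPU,
so they use reduced problem sizes, chosen once as the package's own
desk-scale study design:

- geometry closure: 100 realistic phantoms (2000 frames) at the native
  80×80;
- overfit check: 4 concentric (easy) phantoms at 80×80, 4 frames per
  subject, batch 4, 200 optimizer steps, small network (stem 4/8/16,
  hidden 32, depth 1, decoder 12/12/8/6, regression 4/8/32,
  recurrence 1);
- generalisation check: 20 realistic phantoms rendered at 48×48, 2-fold
  subject-level cross-validation, 15 epochs, 10 frames per subject,
  batch 4 (375 optimizer steps per fold), the same small network.

Desk-scale runs also use desk-scale optimizer settings (larger learning
rates, momentum 0.95, no regression weight decay, global-norm gradient
clipping) because the full-scale defaults are tuned for 500-epoch runs on
145 subjects; the full-scale values remain the `train_config()` defaults.
Two details matter for short runs: the pooled head features are
batch-normalised so the index heads see O(1) between-sample variance
(without it the head learns the cohort mean quickly but deviations very
slowly), and gradient clipping bounds the occasional large phase-loss
gradient on frames near the ED/ES boundary, which otherwise knocks the
momentum buffer off course.

## Numerical choices and degenerate inputs

Dice smoothing 1e-5; cross-entropy probability floor 1e-12; BCE
probability floor 1e-7; z-score deviation floor 1e-8 (constant stacks map
to zero). He initialisation for all convolutions and dense layers.
Degenerate masks (empty cavity, missing ring, broken ring, constant area
series) raise errors with the frame index attached rather than returning
zeros. Empty-vs-empty regions count as Dice 1, empty-vs-non-empty as 0,
so per-class scores remain defined on degenerate frames; Hausdorff
distances are computed on 4-neighbour boundary pixels with the Euclidean
metric and skip classes absent from either mask.

## Known limitations

The engine is CPU-bound and sized for desk-scale experiments: full-scale
training (500 epochs, 145 subjects, the 256-wide transformer) is out of
reach without a GPU framework, so headline clinical accuracies cannot be
reproduced here and are not claimed. Within the desk-scale
cross-validation budget (a few hundred optimizer steps per fold) the
segmentation path converges to held-out cavity Dice above 0.95, but the
regression head remains update-limited: its pooled index correlations and
the phase classifier do not reach the levels a full-length training run
would; the phase in particular requires spatially resolved boundary-motion
features (CLAHE plus per-stack normalisation removes the global-intensity
proxy of the area trajectory) that do not emerge this early in training. The phantom's idealisations mean
that passing tests bound correctness, not clinical performance. The
morphometry assumes a star-convex cavity about its centroid — strongly
non-convex cavities would need a different boundary parameterisation.
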