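---
title: "Methods: multi-feature fusion and SVM for weed and corn seedling detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-feature fusion and SVM for weed and corn seedling detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Precision spraying and precision fertilization both need the same piece of
information: where, in a top-down image of a corn field at the 2--5 leaf
seedling stage, the corn plants are and where the weeds are. `weedsight`
solves this as a two-stage problem:

1. a **leaf classifier** -- corn (+1) versus weed (-1) -- trained on
   size-normalized single-leaf images on zero backgrounds, and
2. a **field detector** that segments vegetation from soil, splits it into
   plant-sized connected regions, and runs the leaf classifier on each
   region.

Corn seedling blades are broad, flat, and carry a combination of regular
texture (parallel veins) and random texture over a comparatively large
area; the common seedling-stage weeds have thin or lobed blades with
finer, more random texture. The feature set is chosen to measure exactly
these cues.

## Leaf descriptors

All descriptors operate on the grayscale (Rec. 601) version of a
256x256-normalized image. Size normalization scales the input uniformly
by `256 / max(H, W)` (bilinear) and fills the remaining canvas with exact
zeros, so leaf shape is never distorted; the scaled content is anchored
at the top-left by default (a centered anchor is available). The choice
of anchor does not affect any of the translation-invariant descriptors
and affects the others identically at train and test time, since every
image passes through the same chain.

* **HOG** (shape/contour): 9 unsigned orientation bins per cell,
  `[-1, 0, 1]` derivative kernels, blocks of 2x2 adjacent cells at
  one-cell stride with L2-Hys normalization (clip 0.2, zero-guarded).
  With 64-pixel cells on a 256-pixel image: `(256/64 - 1)^2 * 36 = 324`
  dimensions. The configuration is the canonical one that reproduces the
  block-dimension arithmetic; the cell-size sweep {8, 16, 32, 64, 128}
  gives {34596, 8100, 1764, 324, 36}.
* **Rotation-invariant LBP** (structural texture): 8-bit codes from the
  3x3 neighborhood (clockwise from top-left, `neighbor >= center` sets
  the bit -- a deterministic tie rule on flat regions). Two rotation-
  invariant reductions are exposed: the classical minimum over circular
  bit-rotations (`rotlbp_code`; the worked neighborhood example 125 ->
  95), and the 10-bin uniform-pattern (riu2) binning used for cell
  histograms, which yields `(256/cell)^2 * 10` dimensions (160 at
  64-pixel cells). Cell histograms are normalized to unit mass so cells
  compare across leaf sizes.
* **Hu moments** (global shape): the seven classical invariants plus the
  eighth, `phi8 = 2*eta11*((eta30+eta12)^2 - (eta03+eta21)^2) -
  2*(eta20-eta02)*(eta30+eta12)*(eta21+eta03)`, all built from classical
  normalized central moments.
* **Gabor bank** (signal-processing texture): 5 wavelengths in a
  geometric progression (4, 4*sqrt(2), 8, 8*sqrt(2), 16 px; one-octave
  bandwidth, aspect ratio 0.5) x 8 orientations (k*pi/8); magnitude of
  the quadrature response, mean-pooled over a 3x3 grid of sub-blocks:
  360 dimensions. These bank parameters are not dictated by the
  dimension contract; they are recorded in the `feature_spec` so any
  trained model carries its exact extraction configuration.
* **GLCM** (statistical texture): 64 gray levels, ordered pairs at the
  0-degree unit displacement by default (45/90/135 available), matrix
  normalized by the pair count; six statistics in fixed order -- energy,
  contrast, correlation (zero-guarded), sum entropy, entropy, inverse
  difference moment. Natural logarithms throughout, `0 log 0 = 0`.
* **GGCM** (gray-gradient statistics): Sobel gradient magnitude
  (edge-replicated borders), max-normalized and quantized to 64 levels,
  jointly histogrammed with 64 gray levels; fifteen statistics. The
  classical statistic list names fourteen; the fifteenth in the standard
  set is the gradient mean square error, which is what this package
  uses -- the full fixed order is small/large gradient dominance, gray
  and gradient nonuniformity, energy, gray and gradient mean, gray and
  gradient mean square error, correlation (covariance form), gray,
  gradient and mixed entropy, inertia, deficit moment. Level indices
  enter the formulas 1-based so the small-gradient dominance of a
  texture-free image is exactly 1, its maximum.

## Fusion and reduction

Strategies are `"+"`-separated descriptor names (`"GGCM+RotLBP"`),
case-insensitive, concatenated in the order written; the 24 strategies
of interest span all singles, pairs, and the larger fusions up to the
867-dimensional five-feature combination. PCA is fit once on the full
concatenated feature matrix (extraction precedes reduction in the
protocol), storing the training mean and an orthonormal
`input-dim x p` projection with a deterministic sign convention
(largest-magnitude loading positive); the identical affine map is
applied to training, validation, and field-region features. A stored
`p x p` matrix could not map `input-dim -> p` when the two differ, so
the full projection is what the model bundle carries. Low-dimensional
descriptors (15 dimensions or fewer) skip PCA by default -- reduction
below such small dimensionalities tends to cost accuracy -- and
`select_retention()` implements the retention sweep (ties to the
smallest `p`).

## Classifier and protocol

Features are standardized per dimension with training-set statistics
(fused descriptors mix magnitudes across orders of magnitude; an SVM on
raw concatenations would be dominated by whichever block is largest).
The SVM is linear by default -- descriptor vectors are high-dimensional
relative to sample counts, where a linear margin is the standard first
choice -- with an RBF option. Labels follow the corn = +1, weed = -1
convention; accuracy is `(TP + TN) / (TP + FP + FN + TN)` with corn as
the positive class. The experiment protocol is a stratified 70/30
split (700/300 per class at 1000 per class), repeated across an explicit
seed list (default `0:9`) with per-run and mean accuracy reported. The
2-D scatter visualization of validation samples, where used, plots the
first two post-PCA coordinates.

## Field detection

Scenes are converted to CIELAB (sRGB, D65) and the per-pixel `a`
(green--red) channel is clustered with k-means, k = 2: vegetation is
green (`a < 0`), soil is not. The foreground is the cluster with the
lower mean `a`; if that mean is not negative the scene is flagged as
vegetation-free rather than force-segmented. `stats::kmeans` with 10
random restarts under a caller seed stands in for a k-means++
initialization: with two well-separated 1-D clusters the restarts make
the outcome effectively deterministic, which is the property that
matters. Components are labeled with 8-connectivity (a 4-connected
labeling plus a diagonal union pass) and components below `min_area`
(default 0.1% of the scene -- soil speckle scale; configurable) are
discarded. Each surviving region is cropped by its bounding box with
out-of-component pixels zeroed, size-normalized, and classified by the
same model bundle (spec -> PCA -> scaler -> SVM) used for leaves, so
train and field distributions match by construction. Annotation draws
2-pixel yellow outlines for corn, red for weeds, later boxes over
earlier. A known limitation carried over from the method itself:
heavily edge-truncated plants (less than roughly a third of the plant
visible) are not specially handled and will classify unreliably.

## The synthetic generator

No leaf or field image set is shipped; a deterministic generator
replaces it. Corn leaves are single broad elongated blades
(reference-scale length 170--230 px, width 55--85 px) with smooth
low-frequency shading and regular parallel vein striping (amplitude
0.25--0.35, period 8--14 px); weeds are 3--5 thin radiating blades
(length 70--120 px, width 13--22 px) dominated by high-frequency
speckle (amplitude 0.28--0.40). Both render at a random working scale,
are cropped to their blade mask, and are size-normalized -- the same
chain a detected field region traverses, so the classifier sees one
distribution. Backgrounds are exact zeros. Field scenes composite
non-overlapping plants onto brown soil with multiplicative
low-frequency noise, darker elliptical clods, and pixel noise; ground
truth records class, tight half-open bounding box, and pixel area, and
plants are re-rendered larger if a draw lands under 0.16% of the scene
area so every planted plant clears the detector's default small-region
threshold.

The `texture_contrast` parameter interpolates every class-specific
parameter range toward the common midpoint: at 1 the classes are fully
themselves; at 0 both classes sample from identical distributions, the
negative control under which classifier accuracy must collapse to
chance. This makes feature relevance itself testable: separation comes
from the texture/shape cues the descriptors measure, not from an
accidental intensity offset.

What the generator does **not** emulate: photometric realism, specular
highlights, sunny/cloudy illumination fields, overlapping or occluded
plants, and real leaf venation geometry. Passing end-to-end checks on
generated scenes therefore demonstrates that the pipeline's stages
compose correctly and that the descriptors separate the texture classes
they claim to separate -- not field-ready accuracy on photographs.

## Numerical choices and test scale

Quantization maps `[0, 255]` to `floor(v * levels / 256)` clamped to
`levels - 1`; gradient quantization max-normalizes first. Entropies use
natural logs with `0 log 0 = 0`. Degenerate inputs are guarded
explicitly: all-zero images raise a moment error, zero-variance
channels flag vegetation-free scenes, constant images produce zero HOG
vectors and unit small-gradient dominance. Every co-occurrence and
moment statistic is tested against an independent double-loop oracle at
1e-10 on toy images, and the LBP reductions are verified exhaustively
over all 256 codes.

Default verification scale, chosen to exercise the full protocol on a
single CPU: 1000 + 1000 generated leaves for the classification check
(70/30 split, GGCM+RotLBP, PCA retention 94), 20 scenes of 2 corn + 4
weeds at 600 x 1024 for detection, 150 + 150 leaves for the negative
control.
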