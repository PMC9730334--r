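---
title: "Leaf-vein morphometry with veinmorph: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf-vein morphometry with veinmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinmorph)
```

## The problem

A semantic-segmentation network applied to a leaf photograph produces a
binary mask of the main vein. Three defects stand between that mask and a
trustworthy measurement. Leaf folds occlude parts of the vein, so the mask
arrives fragmented. Fine interior cavities and rough contours make the
medial-axis skeleton sprout short false branches (burrs) that inflate any
pixel-count length estimate. And a vein that runs at an angle to the image
rows has a per-column contour separation of `T / cos(φ)` for a true
thickness `T`, so the naive vertical separation overestimates width.
`veinmorph` addresses the three in order: convex hull-scan repair, the
F-3MS refinement pipeline, and an angle-corrected width model, with a
scale bar (mm·pixel⁻¹) converting pixels to physical units at the end.

All rasters are integer matrices in the screen coordinate system: `m[row,
col]`, x = column rightward, y = row downward, foreground = 1. Files are
written with foreground 255 for viewability.

## Convex hull-scan repair

Fragments are located by 8-connected component labeling (8-connectivity so
thin diagonal strokes do not fragment further). For each pair of
substantive components whose boundary-to-boundary Euclidean distance is at
most `maxGapPx`, the two nearest boundary points define a local window
(expanded by `windowMarginPx`); the boundary pixels of both components
inside the window, plus all pixels of noise components (area below
`minFragmentPx`) inside it, form the point set of that gap. The minimum
convex polygon of the set is built by a Graham scan — anchor at minimal x
(ties by minimal y), polar-angle sort about the anchor with nearer points
first on ties, and a sweep that keeps a candidate only on a strictly
positive cross product, so collinear points never survive as vertices —
filled (edge rasterization plus the convex interior), and unioned with the
mask. Repair is therefore extensive, never increases the component count,
and is idempotent once the gaps are closed.

The gap-localization rule is a design choice of this package: a convex
hull over the *whole* mask would convexify every curved vein, so the hull
is computed only over the local gap neighborhood. Defaults (`maxGapPx =
40`, `minFragmentPx = 25`, `windowMarginPx = 10`) are sized for main-vein
masks at the working resolution of roughly 500-pixel vein extents and are
exposed as `RepairParams`.

One printed convention deserves a note: the sign rule accompanying the
hull formula in its source describes a positive cross product as marking
interior points, while the worked construction sequence deposits vertices
on positive turns; the construction sequence is followed here.

## The F-3MS refinement pipeline

`f3msPipeline` composes, in order:

1. **Flood-fill hole closing** (`fillHoles`): flood the background from
   every border pixel (4-connectivity for background), NOT the result, OR
   with the original. Interior cavities — and only they — become
   foreground; the op is extensive and idempotent.
2. **Opening** (`openMask`, default 3×3 square): removes isolated specks
   smaller than the element; anti-extensive.
3. **Weighted grayscale** (`toGray`): `0.299 R + 0.587 G + 0.114 B`,
   rounded half away from zero (pinned so tests are bit-exact). Binary
   input is first rendered red-on-black so the stage order of the original
   protocol is preserved; RGB input is binarized (grayscale + Otsu) before
   stage 1.
4. **Median filtering** (`medianFilterImage`, default 5×5): smooths the
   vein contour; border policy is edge replication (pinned). The 5×5
   default is the kernel that maximized measurement accuracy in the
   kernel-size ablation; 3×3 under-smooths rough contours and 7×7 starts
   eroding genuine vein shape.
5. **Otsu thresholding** (`otsuThreshold`): maximizes the between-class
   variance `w0 w1 (u0 − u1)²` over all 256 candidate levels (ties to the
   smallest level; a constant image warns and yields an all-background
   mask). The criterion is stated in the sources only through its class
   identities (`w0 + w1 = 1`, `w0 u0 + w1 u1 = uT`); the canonical
   between-class variance is the objective implemented, and an exhaustive
   search over all levels serves as the test oracle.
6. **Morphological skeleton** (`morphSkeleton`): the Lantuéjoul
   construction `S(A) = ∪_k [(A ⊖ kB) − (A ⊖ kB) ∘ B]`, iterated until the
   erosion is empty, with a 3×3 cross element by default ("square"
   available). Erosion treats pixels outside the raster as background, so
   the iteration always terminates. The construction satisfies the exact
   reconstruction identity `A = ∪_k (S_k ⊕ kB)`, which the tests verify on
   every mask they touch.

Burr suppression is a property of stages 1–5, not of the skeleton
operator: closing the cavities and smoothing the contour removes the
features that seed spurs. The tests state this directionally — mean
skeleton endpoint count after the full pipeline is no larger than after
bare skeletonization on the same degraded phantoms — rather than as a
fixed count.

Two caveats about the skeleton operator are worth knowing. It is not
guaranteed connected (residuals at different erosion depths can be
disjoint), and on a flat band spanning an *even* number of rows its final
residual is two pixels thick, because the opening of a two-row band by a
3×3 element is empty. Both matter for measurement and drive the choices
below.

## Length and width measurement

`measureVein` composes repair, F-3MS, axis normalization and the width
model. The measured object of the geometric model is a *single-valued
skeleton line* `y_s(x)` — one ordinate per column — and the package
constructs it explicitly:

* **Axis normalization.** The orientation of the skeleton's principal
  axis (from second-order moments) is removed by nearest-neighbor
  rotation, and the refinement is re-run in the rotated frame (the
  rotation roughens band edges; re-refining keeps the skeleton burr-free
  there). Pixel-count length only approximates arc length for
  near-horizontal lines — a line at angle φ has `cos(φ)` times fewer
  pixels than its length — so normalization is what makes the estimate
  tilt-invariant.
* **Skeleton line** (`skeletonLine`): each column of the skeleton is
  collapsed to its rounded mean row. This is the same per-column
  reduction the width model uses, and it neutralizes the even-height
  double-thickness artifact above. Length = line pixel count × scale bar;
  no √2 weighting of diagonal steps, consistent with the pixel-count ×
  scale-bar arithmetic of the published measurement tables.
* **Contours** (`cannyContour`, `contourFunctions`): on a binary mask,
  edge detection reduces exactly to "foreground pixel with a background
  4-neighbor", which is implemented directly (parameter-free and
  bit-exact). Per column, `u(x)` and `v(x)` are the extreme contour rows;
  columns with fewer than two contour pixels are omitted.
* **True width** (`trueWidthProfile`): per column,
  `halfSep = (v − u + 1) / 2` and `trueWidth = halfSep · cosθ` with
  `cosθ` from central differences of the ordinate sequence. Two
  discretization choices are deliberate:
  * the `+1`: integer contour rows sit half a pixel inside the physical
    boundary on each side, so the raw `v − u` underestimates the span by
    one pixel — a systematic `−1/T` relative bias (about −5% at T = 18)
    that would otherwise dominate the error budget;
  * the ordinate entering `cosθ` is smoothed by a short running mean
    (default 9 columns): the discrete midline carries ±0.5 px
    quantization jitter, and a two-column derivative baseline turns that
    jitter into a downward cosine bias of 5–10% (Jensen's inequality: the
    mean of `1/sqrt(1 + s²)` over a jittering slope s lies below its
    value at the mean slope). The half-separation itself is never
    smoothed.

  The ordinate is the skeleton midline by default (`mode = "midline"`).
  The literal reading of the model's point coordinates would use the
  half-separation itself as ordinate (`mode = "half_separation"`); under
  it a tilted constant-width band has a constant ordinate, receives no
  correction, and its width is overestimated by `1/cos(φ)` — the
  geometry figure accompanying the model draws the skeleton as the
  midline, which is why midline is the default. Both modes are
  implemented.
* **Reported width** is the half-separation-based quantity exactly as the
  model defines it — about half the anatomical vein thickness — matching
  the magnitudes of the published width tables; `fullWidth = TRUE`
  doubles it.

Degenerate inputs error early and explicitly: empty masks, empty
skeletons, profiles with fewer than three shared columns.

## Synthetic phantoms: what they are and are not

`generatePhantom` rasterizes a capsule — every pixel whose center lies
within `T/2` of a centerline polyline — and records exact truth: polyline
arc length, thickness, half-width. The centerline is placed at a
half-pixel row offset, the generic position; a lattice-aligned centerline
is a measure-zero special case whose closed boundary inequality covers one
extra pixel row. `degradePhantom` removes seeded transverse gaps (slabs of
arc-length extent `gapLenPx`), punches 1–2 px interior pinholes, and
sprinkles isolated background speckle (kept ≥3 px from the band and from
each other, so a 3×3 opening provably removes it). All randomness flows
from the spec's single integer seed; identical specs produce bit-identical
phantoms.

The default degradation — two 8 px gaps, five pinholes, speckle density
5·10⁻⁴ on bands of length 300–500 px, thickness 12–24 px, tilt 0–30° —
defines the conditions under which the toolchain is exercised end to end.
On those conditions the recovery errors measured by the acceptance script
are about 2–3% mean absolute for both length and width. Skeleton
end-shortening (erosion retracts the line by roughly `T/2` at each
extremity, partially offset by the capsule's rounded caps) is the dominant
length error and is what the tolerance absorbs.

What the phantoms do *not* emulate: photometric texture, uneven
illumination, tapering or branching veins, curved occlusion boundaries,
and segmentation-network failure modes other than fragmentation and
pinholes. Passing the phantom suite therefore demonstrates the geometry of
the toolchain, not segmentation quality on real leaves.

Augmentation (`augmentPair`: scale, translate, mirror, rotate; masks
nearest-neighbor so they stay binary) and a PASCAL-VOC layout writer
(`writeVocDataset`: JPEGImages/, SegmentationClass/, ImageSets splits by a
seeded shuffle with largest-remainder 8:1:1 rounding) make small training
fixtures reproducible.

## The segmentation-network contract

The deep model itself is described at shape level — which is all that is
verifiable without the original dataset. `buildModel` wires the standard
inverted-residual stage table (17 blocks, truncated at the 320-channel
stage) with strides converted to dilation once the configured output
stride (8 or 16) is reached; at 512×512 input and stride 16 the deepest
map is 32×32×320 and the stride-4 skip is 128×128×24. The ASPP head uses
five branches (1×1, three dilated 3×3 at rates 6/12/18 for stride 16 and
12/24/36 for stride 8, global pooling) fused to 256 channels, and the
decoder projects the 24-channel skip to 48 before concatenation — the
canonical dimensioning, which the network description names but does not
dimension. The depthwise-separable cost model is implemented in the
standard form `DK²·M·DF² + M·N·DF²` (one printed variant of the first term
omits a `DF` factor; only the standard form is consistent with the ratio
`1/N + 1/DK²` that accompanies it).

Two evaluation metrics come from a truth-by-prediction confusion matrix:
mean IoU, `mean_i TP/(TP+FP+FN)`, and mean pixel accuracy implemented as
the per-class one-vs-rest accuracy `(TP+TN)/(TP+TN+FP+FN)` — the form the
defining equations give, although their prose also describes a per-class
recall; the two disagree in general and the equation form is implemented.
Classes absent from both truth and prediction are excluded from the means.

The optimizer is the bias-corrected Adam recurrence, reproduced exactly
and verified against an independent recurrence to 1e-12 over 50 steps. The
training protocol (100 epochs, backbone frozen for the first 50 at batch
8, unfrozen at batch 4, lr 0.001 with a cosine scheduler, weight decay
5e-4) is stored in `TrainConfig`; `gamma = 0.94` is a step-decay rate that
is stored but unused under the cosine scheduler, as configured. Since no
deep-learning framework is part of this stack, `trainSmoke` exercises the
schedule and optimizer on a pixelwise logistic segmentation surrogate with
analytic gradients (noisy intensity plus box-mean features, an affine
"backbone" frozen during phase one, binary cross-entropy with the
configured weight decay); it validates the training wiring, not the deep
network, whose contract is `buildModel`.

## Problem sizes and numerical conventions

The test suite runs phantom geometry at bands of 80–500 px length and
9–24 px thickness, 20-phantom sweeps for the end-to-end and burr
properties, 200 random instances for the hull oracle and 100 for the Otsu
oracle; the whole suite completes in well under a minute, and
`scripts/acceptance.R` in about twenty seconds. Conventions pinned for
reproducibility: grayscale rounding half away from zero, median-filter
edge replication, Otsu ties to the smallest level, 8-connectivity for
vein content and 4-connectivity for background flood fill, and a single
named seed per phantom with no global RNG leakage (`withSeed` saves and
restores the caller's RNG state).

## Known limitations

* The morphological skeleton is not guaranteed 1-px connected; the
  single-pixel skeleton line is obtained by per-column reduction, which
  assumes a dominantly horizontal (axis-normalized) vein and would
  misrepresent a vein that doubles back on itself in x.
* One vein per mask is assumed: no branching topology, no
  secondary-vein analysis.
* The repair hull is convex per gap window; a strongly curved occlusion
  boundary can be slightly over-filled (no concave/alpha-shape repair).
* Width is a half-separation-based quantity; anatomical full thickness
  requires `fullWidth = TRUE`.
* 8-bit single-channel or RGB rasters only; no 16-bit or multispectral
  imagery.
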