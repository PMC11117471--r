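---
title: "Methods: region-proposal nodule detection on synthetic CT phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-proposal nodule detection on synthetic CT phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungrpn)
```

`lungrpn` implements the components of a two-stage pulmonary-nodule
detector — lung-field preprocessing, clustered anchor priors, region-proposal
geometry, attention-gated patch classifiers, and detection metrics — in a
form that can be exercised end to end on synthetic CT phantoms with exact
ground truth. This vignette records the models, the tunable parameters and
their defaults, the numerical conventions, and the design choices that were
genuinely open, so that a reader can judge what the test suite does and does
not establish.

## The phantom generator

Real thoracic CT slices are 512 × 512 rasters of Hounsfield units (HU), a
calibrated radiodensity scale on which air sits near −1000, aerated lung
tissue near −850 to −700, soft tissue near 0 to +60, and cortical bone above
+300. The generator (`phantom_spec()`, `make_phantom_slice()`) builds the
minimal geometry that exercises HU-threshold preprocessing: an elliptical
soft-tissue body (+40 HU) on an air background (−1000 HU), two elliptical
lungs (−850 HU) kept clearly apart at the midline, optional rib-like bone
arcs (+700 HU) along the body rim, and nodules as disks of −50 HU — a
soft-tissue-like density that is bright against lung air, which is exactly
the contrast a detector exploits. Nodule diameters are at least 3 mm, the
conventional lower bound for annotated nodules in public lung-CT archives.

The default slice geometry is 512 px at 0.7 mm/px, matching the archive
dialect the I/O layer emulates (MetaImage `.mhd`/`.raw` volumes plus an
annotation CSV of world-coordinate centres and diameters, world origin at
the volume corner). The demo pipeline and the acceptance run use 128 px
phantoms at 1.0 mm/px — the same anatomy at a quarter the linear scale —
so that a 200-slice run with two classifier branches finishes in about two
minutes on one CPU; the package reports this as its demo scale.

Additive Gaussian HU noise is available but **off by default**: noise-free
compartments make threshold-level tests exact. What the phantom does *not*
model: parenchymal texture, vessels and airways, partial-volume blur,
juxtapleural (wall-attached) nodule shapes, scanner artefacts. Tests that
pass on phantoms therefore validate the *logic* of each stage (thresholds,
morphology, geometry, accounting), not performance on clinical images.

Ground-truth boxes are the analytic tight pixel boxes of each nodule disk
(`floor(c − r), ceiling(c + r)` in pixel units, 0-based half-open); an
independently written rasterizer in the test suite confirms they bound the
painted pixels to within one pixel of discretization.

## Preprocessing

The lung-field pipeline follows the classical HU recipe: calibrate
(`HU = raw × slope + intercept`), binarize air-like pixels (`HU < −400`, a
threshold placed in the wide gap between lung air ≈ −850 and soft tissue ≈
+40), remove air components connected to the image border (the exterior),
split the surviving interior components into left and right lungs by
horizontal position, and expand each lung so wall-attached nodules stay
covered. "Expansion" is not pinned down in the descriptive literature; this
package uses a morphological closing (disc, radius 5 px), a convex-hull
fill per lung, and a final dilation margin (disc, radius 2 px). The closing
bridges concavities, the hull covers indentations where nodules could abut
the wall, and the dilation adds an explicit safety rim — a closing alone
would not expand a convex lung at all. On noise-free phantoms the resulting
mask covers 100% of ground-truth nodule boxes while staying within 1.3× the
analytic lung area.

Display windowing maps `(−1200, 600)` HU linearly onto `[0, 255]` with
half-up rounding and clipping — a window wide enough to keep lung detail
and bone on one scale. Bone removal zeroes pixels above +300 HU together
with gradient-magnitude edge pixels (Sobel, Otsu threshold) inside a 2-px
neighbourhood of the bone, and leaves bone-free slices bit-identical.

Connected components use 8-connectivity; all morphological elements are
symmetric discs, which is what makes the whole pipeline equivariant under
horizontal mirroring — a property the tests check exactly, since CT scans
can be stored flipped.

## Anchor priors by clustering

Detectors work best when their anchor shapes match the size distribution of
the objects. Given a population of box shapes (width, height), the package
fits `c` anchor shapes either by k-means or by fuzzy c-means (FCM). The FCM
membership of point *j* in cluster *i* is

$$u_{ij} = \Bigl[\sum_{k=1}^{c}\bigl(d_{ij}/d_{kj}\bigr)^{2/(m-1)}\Bigr]^{-1},$$

alternated with weighted-mean centre updates (weights $u_{ij}^m$). The
fuzzifier defaults to `m = 2`; as `m → 1⁺` the maximum-membership
assignment collapses onto the crisp k-means partition, which the tests
verify on separated clusters. The objective
$J = \sum_j\sum_i u_{ij}^m d_{ij}^2$ is recorded every iteration and is
non-increasing. Distances are Euclidean in (width, height) pixel space by
default — the clustering space is a genuine design choice, so a `1 − IoU`
distance is exposed as an option (`dist = "iou"`). A point coincident with
a centre takes membership 1 on the lowest-index coincident centre.
Convergence: maximum centre displacement below `tol = 1e−5`, cap 300
iterations, k-means++-style seeding under the caller's seed.

k-means is Lloyd's algorithm written out (assignment / mean update to a
fixpoint), with an emptied cluster reseeded on the farthest point, keeping
the best of 10 seeded restarts — and, on inputs of at most 10 points, the
best over every distinct initial subset, which is how the test suite can
compare it against an exhaustive-partition oracle exactly. Anchor quality
is summarized by `mean_best_iou()`: the mean, over boxes, of the best IoU
any anchor achieves when box and anchor are co-centred. This is the
package's own instrumentation for comparing cluster counts, not a
published quantity.

## Region-proposal geometry

Boxes are 0-based, half-open pixel rectangles throughout; areas are
`(x_max − x_min)(y_max − y_min)`. Anchors are tiled at cell centres
`((j + 0.5)s, (i + 0.5)s)` for stride `s`. Labeling uses the conventional
two rules: IoU ≥ 0.7 against any ground-truth box makes an anchor positive,
best IoU < 0.3 makes it negative, anything else is ignored — and every
ground-truth box recruits its argmax-IoU anchor as positive even below the
threshold, so no object is left without a positive anchor. Offsets use the
standard parameterization `((Δcx)/w_a, (Δcy)/h_a, log(w_g/w_a),
log(h_g/h_a))`, whose encode/decode round-trip is exact to floating point.

Non-maximum suppression is greedy by descending score. Ties are broken by
box coordinates (lexicographic on `x_min, y_min, x_max, y_max`) rather than
by input position: coordinate ties make the survivor set a pure function of
the box set, so suppression is deterministic *and* independent of input
order, which an index-based tie-break cannot guarantee. Proposal selection
is suppression followed by truncation to the top `N` (default 300; the
demo pipeline uses 12 per slice).

## Attention blocks

Three gating blocks operate on `C × H × W` feature maps in inference mode:

* **SE** — global average pool per channel, bottleneck
  (`r = ceiling(C/ratio)`, clamped to ≥ 4), hard-swish, sigmoid channel
  gates.
* **CA-I** — 1D average pooling along each spatial direction, the two
  descriptor matrices concatenated through a shared bottleneck with
  inference-mode batch normalization (stored statistics, so forwards are
  deterministic) and hard-swish, then split into per-row and per-column
  sigmoid gates; the output is `x · g_row · g_col`.
* **CA-II** — CA-I with each directional descriptor formed from average
  *and* maximum pooling. The two descriptors are combined by their *mean*
  rather than their sum: averaging makes CA-II collapse exactly onto CA-I
  on spatially constant inputs (where max = avg), which is the natural
  degenerate-case contract for a pooling enrichment — a sum would double
  the descriptor scale and break that equivalence.

Zero-initialized parameters give exactly neutral gates (sigmoid(0) = 0.5),
so SE scales its input by 0.5 and the two-gate coordinate variants by 0.25
— a closed-form check the tests assert bitwise. Because every gate lies in
(0, 1), attention can only attenuate; output shape always equals input
shape.

## Scaled-down classifiers and the demo trainer

The four backbone families are implemented as small pure-R forward passes
that keep each family's defining structure: residual stages
(`relu(x + conv(relu(conv(x))))`), densely connected stages whose input
channel count grows linearly at the growth rate, depthwise-separable
stages (per-channel 3 × 3 followed by pointwise 1 × 1 — provably fewer
parameters than the equivalent standard convolution), and mixed-kernel
stages (channel groups convolved depthwise at 1 × 1 / 3 × 3 / 5 × 5 and
re-mixed pointwise). Channel widths and depths scale with
`width_scale`/`depth_scale`; every model ends in a 2-neuron head (nodule
vs non-nodule), and an attention block can be inserted after each stage.

Full network training is out of scope on a CPU, so `train_demo()` freezes
the backbone at its seeded random initialization — random convolutional
features — and fits only the softmax head by full-batch gradient descent
on cross-entropy, with inverse-class-frequency sample weights (candidate
sets are heavily negative-dominated) and a small ridge penalty. This keeps
the contracts that matter testable: determinism under a seed, a constant
loss trace at zero learning rate, monotone-in-expectation loss on
separable data (> 0.9 training accuracy on a bright-blob patch set), and a
structured `lungrpn_divergence` error on non-finite loss. It does *not*
emulate learned feature quality; pipeline indicators should be read
accordingly.

Multi-backbone fusion is score-level: `union_positive` accepts a candidate
when either branch exceeds the threshold (so its positive set contains each
branch's — fused sensitivity can never fall below a branch), `mean_score`
averages then applies a strict `>` threshold. Both readings of "combine
the two best backbones" are implemented because the source idea is
ambiguous between score-level and proposal-level union; `union_positive`
is the default.

## The demo pipeline and its accounting

`cmd_pipeline()` chains the stages: preprocess every slice; fit anchor
shapes to the annotated box population (FCM, `K = 5`, `m = 2` by default);
tile the anchors at stride 2 and score each box by a training-free
centre-surround contrast (mean masked intensity inside the box minus a
surrounding ring, via an integral image) — bright compact structures in
the lung score high; suppress and keep the top 12 per slice; classify a
16 × 16 patch per candidate under slice-level 5-fold cross-validation
(train folds fit the head, test folds are scored); optionally fuse a
second backbone branch; and count the confusion table.

A candidate counts as hitting a nodule at IoU ≥ 0.3 — deliberately below
the 0.5 common for large natural objects, because at stride 2 a 4-px
nodule box can be off-centred by a pixel and still deserves credit (its
IoU tops out near 0.4). True negatives are only meaningful at candidate
level, so the negative universe is explicit: per slice,
`negatives_evaluated = candidates − TP`, hence `TN = negatives − FP ≥ 0`
by construction. Indicators with zero denominators are reported as `NA`,
never silently as 0. Offset regression is not exercised in the demo
pipeline (proposals are raw anchors); encode/decode is tested separately.

## Published-table worked examples

`nodule_benchmark_tables()` embeds the indicator rows of a published
LUNA16 benchmark study (four backbones × two clustering methods × cluster
counts, plus attention variants) as fixtures. The F1 column of such a
table must equal the harmonic mean of its own precision and sensitivity
columns up to input rounding (±1e−4 for 4-decimal inputs);
`check_f1_consistency()` verifies this identity row by row. 39 of the 40
rows reproduce; one row (MobileNet with k-means, K = 5) is internally
inconsistent as printed — recomputation gives 0.9169 against a printed
0.9218 — and the checker reports it as a failure, which is the correct
behaviour for a consistency instrument. The tests pin both the 39 passes
and that one flagged row, plus a perturbation negative control.

## Numerical conventions and limitations

* Rounding is half-up where pixel values are produced; coordinates are
  0-based; boxes are half-open.
* All stochastic steps (phantom sampling, clustering initialization, fold
  assignment, parameter initialization) take explicit integer seeds and
  are bit-reproducible.
* MetaImage I/O supports the uncompressed little-endian subset
  (MET_UCHAR/SHORT/FLOAT/DOUBLE) that lung-CT archives use; compressed or
  big-endian volumes are rejected, and DICOM is out of scope.
* The phantom's simplifications (no texture, convex lungs, disk nodules)
  mean detection indicators from the demo pipeline characterize the
  pipeline's plumbing, not clinical accuracy; the published-table
  examples are consistency checks on printed numbers, not reproductions
  of trained-model performance.
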