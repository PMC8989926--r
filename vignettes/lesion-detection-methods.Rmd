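---
title: "Methods: two-stage lesion detection on ultrasound speckle phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage lesion detection on ultrasound speckle phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uslesion)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, how they were resolved, and what the synthetic
evidence does and does not show.

## The detection model

The pipeline assumes one lesion (or none) per grayscale B-mode frame, that
the lesion is hypoechoic — darker than the surrounding tissue — and that it
sits in the upper part of the scan, above the posterior region.  Under
those assumptions detection proceeds in five stages: preprocessing,
unsupervised region proposal, a confidence-gated RoI classifier, iterative
bounding-box regression, and IoU-clustering aggregation.  Each stage is an
exported function (`preprocess()`, `propose_rois()`,
`score_rois()`/`filter_rois()`, `iterate_regression()`,
`aggregate_boxes()`), and `detect()` composes them.

Boxes use a 0-based, half-open pixel convention: `B = (x, y, w, h)` covers
columns `[x, x + w)` and rows `[y, y + h)`, so an integer box has area
exactly `w·h`, and evaluation uses continuous (non-rasterized) areas
because regression produces fractional coordinates.

## Preprocessing

Order is fixed: histogram equalization on the raw 8-bit histogram, per-image
min–max normalization to `[0, 1]`, wavelet shrinkage denoising, then
removal of the bottom `clip_fraction` of rows (default 0.3, the posterior
region).  Only bottom rows are discarded, so box coordinates on the clipped
frame equal original-frame coordinates; the row count kept is
`round((1 − f)·H)` with half-away-from-zero rounding, a deliberate,
documented tie rule.

No 2-D wavelet transform was available among the package's dependencies,
so the denoiser implements a separable periodized orthonormal Daubechies
transform itself (`haar`, `db2`, `db4`; default `db4`, 3 levels).
Periodized orthonormal filters reconstruct exactly for any even length
(their even-lag autocorrelations vanish under folding), so the only hard
constraint is `2^levels ≤ min(H, W)`; images are mirror-padded to a
multiple of `2^levels` and cropped back.  Detail subbands are
soft-thresholded BayesShrink-style: the noise scale is
`median(|HH₁|)/0.6745`, each subband's threshold is `σ²/σ_x` with `σ_x`
the subband signal scale, and subbands indistinguishable from noise are
zeroed.  This is standard practice for speckle-corrupted images; the
wavelet family and depth are exposed as configuration.

## Region proposal

The Canny chain uses the printed 3×3 Sobel pair in which the kernel named
*x* responds to intensity change down the rows and the kernel named *y*
across the columns — the transpose of the naming some texts use.  The
kernels are applied exactly as printed; gradient magnitude and the
suppression geometry are unaffected, and the direction angle is computed
accordingly (`atan2(g_row, g_col)`).  Non-maximum suppression quantizes
direction to four sectors (nearest-neighbor, no interpolation) and keeps a
pixel only when its magnitude *strictly* exceeds both neighbors along the
gradient direction, so plateaus die.  Hysteresis marks magnitudes above
`canny_high` strong and `[canny_low, canny_high]` weak; weak pixels
survive only when 8-connected, possibly transitively, to a strong pixel.

The initial segmentation for selective search is not dictated by the
method and was the largest open design point.  Non-edge pixels are
labelled by connected components and edge pixels are then attached to
their nearest component (chessboard-distance layers, ties to the lowest
label).  Components deliberately use **4-connectivity**: thinned contours
are 8-connected curves, and by the standard connectivity duality an
8-connected closed curve separates the plane only for 4-connected regions.
With 8-connected regions the interior of every thin contour leaks through
its diagonal steps, and on phantoms the lesion fused with the background.
For the same reason the final edge map is thickened by `edge_dilate`
rounds of 8-neighborhood dilation (default 1) before segmentation, which
closes the one-pixel contour gaps speckle punches in the ridge.

Similarities follow the canonical selective-search forms: histogram
intersection of 25-bin intensity and 8-orientation × 10-bin
gradient-magnitude histograms, `s_size = 1 − (|i|+|j|)/A`, and
`s_fill = 1 − (area(BB_ij) − |i| − |j|)/A` clamped to `[0, 1]`.  The merge
loop is run over **all** region pairs, not only adjacent ones — a
deviation from canonical selective search, kept because the procedure is
specified that way here; it guarantees exactly `n − 1` merges.  Argmax
ties break to the lexicographically lowest id pair, and a merged region
takes id `max + 1`, making the hierarchy fully deterministic.  Proposals
are the deduplicated boxes of every region that ever existed, minus boxes
smaller than 16 px a side or covering more than 95% of the frame; if that
filter empties the list (a featureless frame proposes only the whole
image), the whole-frame box is returned so every image has a candidate.

Scale parameters are method tunables, not values inherited from any
source: `gaussian_sigma = 1.8` px and hysteresis thresholds `0.08/0.2` on
the normalized image were chosen by measuring proposal recall on seeded
phantom datasets and are ordinary configuration.

## Classification gate

The gate keeps RoIs whose lesion probability is strictly greater than 0.9;
an image where nothing passes produces no detection, which is the designed
behavior on normal scans.  Three classifier implementations satisfy the
same contract: a constant stub, an oracle that maps IoU-with-truth through
a steep logistic (`plogis(25(J − 0.25))`) plus a small deterministic
perturbation — used to test the pipeline independently of classifier
quality — and a trainable model.  The trainable model is a
single-hidden-layer `nnet` on 12×12 bilinear crops of candidate boxes;
candidates are jittered truth boxes and random background boxes, labelled
positive at IoU ≥ 0.5 and negative below 0.2 (the same bounds the
evaluation and the regression loss use), with the in-between band
discarded.  A compact network is an honest desk-scale model for this
separable problem — lesion crops are dark, background crops bright — and
keeps training in seconds on one CPU.

## Iterative bounding-box regression

The encode/decode pair is taken as exact inverses: the offset denominators
are the source box's own `w, h`, and decoding is
`(x + t_x w, y + t_y h, w e^{t_w}, h e^{t_h})` with natural logarithms.
Any consistent reading round-trips, but only this one makes the printed
decode invert the printed encode, and it matches the iterative-regression
lineage this design descends from.  The stepped target
`Φ(B, G, s) = B + (G − B)/(S − s + 1)` telescopes: hitting every stepped
target lands on `G` in exactly `S` steps, for any `S ≥ 1`.  `S` defaults
to 4 — small enough for desk-scale runtimes, large enough that the
trajectory is visibly incremental — and is configurable.  The training
loss is smooth-L1 on `(predicted δ − δ to Φ)`, per component, with boxes
below IoU 0.2 against truth masked out entirely.

The trainable regressor is one ridge-regression head per step on context
features: the box expanded 2× about its center, resampled to 12×12, plus
the darkness-centroid and darkness-spread moments of that window (which
locate a hypoechoic mass relative to the box) and the log box dimensions.
During training each step's input boxes are the previous step's targets
(teacher forcing); prediction rolls the heads out sequentially on the
model's own outputs.  Per-step heads fit the stepped-target structure
naturally — each step regresses a different fraction of the remaining
correction.

## Aggregation

Clusters are seeded by the unassigned box nearest the image center
(Euclidean distance of box centers, ties to the lowest input index); the
membership sweep over remaining boxes repeats to a fixed point, so joining
is transitive and independent of input order — a single pass would make
membership order-dependent, and nothing in the procedure suggests that is
intended.  Reduction repeatedly merges the highest-IoU pair: intersection
at J ≥ 0.7, smallest enclosing box at 0.5 ≤ J < 0.7, merged confidence the
pair's maximum.  Because intersections shrink boxes, a cluster can reach a
state where no pair clears 0.5 — a case the procedure leaves unspecified;
the reducer then drops the lowest-confidence member (ties to the
latest-entered) and continues, which guarantees termination.  When several
clusters tie for the largest size, all are reduced and the most confident
result wins, ties again to the center.  All tie rules are deterministic by
construction, and the whole stage is cross-checked in the tests against an
independently coded literal transcription of the procedure on hundreds of
fuzzed instances.

## Evaluation

One predicted box (or none) per image.  IoU strictly above `tp_jaccard`
(0.5) is a TP; any other prediction is an FP, and a truth-bearing image
without a TP adds an FN — so a wrong box on a lesion image counts both an
FP and an FN, and with one prediction per truth image FP = FN and
precision = recall.  A prediction on a normal image is an FP; a silent
normal image contributes nothing (TN ≡ 0).  IoU exactly 0.5 counts FP — a
literal reading of "larger than", measure-zero for continuous boxes.
Zero-denominator ratios are reported as 0 and flagged in `undefined`
rather than as `NaN`.

## The phantom generator

The phantom emulates the features each stage must confront: a smooth
tissue field (±8% large-scale variation) at echogenicity 0.6; a
rotated-ellipse lesion at level 0.2–0.35 (always darker than tissue;
semi-axes ≥ 4 px); unit-mean gamma speckle (shape 8, lightly correlated)
applied multiplicatively to the clean field, so `image/clean` has unit
mean everywhere; an optional acoustic-shadow streak below the lesion
(strength 0.55, width 0.7 of the lesion width); and a posterior band over
the bottom 30% of rows at 0.35 attenuation, which exercises the clip.
Lesions are constrained to fit above the band, mirroring the anatomical
prior the clip relies on.  Frames default to 128×128 px — small enough
that the full pipeline runs in fractions of a second per image, large
enough that a 16–32 px lesion has realistic proportions.  Everything is a
pure function of an integer seed.

What the phantom does *not* emulate: scan-cone geometry, depth-gain
compensation, refraction and reverberation artifacts, posterior
enhancement, multi-focal disease, and real lesion morphology (spiculation,
angular margins).  Passing tests on phantoms therefore demonstrate the
pipeline's mechanics — proposal coverage, gating, convergence of the
regression, determinism — not clinical performance.

## Problem sizes and tolerances

The test suite and the acceptance script run at sizes chosen to exercise
every stage while staying comfortable on a single CPU: 1,000 random box
pairs for transform round-trips (tolerance 1e-9, the scale of accumulated
double rounding), 500 fuzzed instances for the aggregation oracle, 50
random grids for the hysteresis oracle, 50 phantoms for proposal recall,
100 for the oracle-driven end-to-end rate, and 200 phantoms (160/40 split)
for the trained models.  Training set sizes and model capacities are
deliberately modest; they are stand-ins for full-scale backbones, not
attempts at state-of-the-art accuracy.

## Known limitations

* **Acoustic shadow.** A shadow streak attached below the lesion is as
  dark as the lesion itself, so no intensity edge separates them; the
  contour-based initial segmentation then fuses lesion and streak into one
  elongated region whose bounding box overlaps the truth poorly.  On
  shadowed phantoms, proposal recall drops to roughly a third of its
  shadow-free value (the acceptance script reports both numbers, and a
  dedicated test pins the degradation).  An intensity-quantile refinement
  of the initial segmentation was prototyped and rejected: several times
  slower and still unable to split the near-zero-contrast interface.
  Shape-prior segmentation or a learned proposal stage would be the honest
  fix.
* **One lesion per image.** Aggregation returns a single box by
  construction; multi-focal disease is out of scope.
* **All-pairs merging** costs O(n²) similarities; it is fine at the
  region counts edge-based segmentation produces on 128 px frames
  (tens to low hundreds) but would need locality restrictions on large
  frames.
* **Desk-scale learners.** The `nnet` classifier and ridge regressor are
  contracts-first stand-ins; swapping in a deep backbone only requires
  implementing the two-function interfaces (`score`, `predict`).
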