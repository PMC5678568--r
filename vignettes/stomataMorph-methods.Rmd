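---
title: "Detecting stomata and measuring pore morphology: models and design choices"
author: "stomataMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stomata and measuring pore morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plant physiologists infer water stress and gas-exchange behaviour from the
morphology of stomata — the pores on the leaf epidermis, each flanked by a
pair of guard cells. The standard data source is a light-microscope image of
a nail-polish imprint of the leaf surface: a large, feature-rich field
containing tens of stomata among epidermal cell walls, veins and dust.
Manual tracing of pore outlines in such images is so slow that studies
typically measure only a handful of stomata per image. `stomataMorph`
automates the whole chain: find every stoma in the micrograph, then measure
each pore's area, axis lengths and eccentricity — including pores whose
boundary is only partially visible, which manual and earlier automated
workflows simply discard.

## Detection: an attentional cascade over HOG features

Detection slides a fixed square window (default 96 px at the package's
synthetic scale) over the image at several pyramid scales (defaults 0.8, 1,
1.25) and asks a trained classifier whether the window holds a stoma. The
classifier is an *attentional cascade*: an ordered list of boosted stages,
each a weighted vote of depth-1 decision stumps on single components of the
window's histogram-of-oriented-gradients (HOG) descriptor. A window is
rejected by the first stage whose vote falls below the stage threshold, so
the overwhelmingly stoma-free majority of windows costs only a few stump
evaluations; the implementation exploits this with per-orientation-bin
integral images and lazy, per-feature descriptor evaluation.

The HOG descriptor uses unsigned gradient orientations over [0°, 180°),
hard-binned into 9 bins per 8 px cell, with overlapping 2×2-cell blocks
L2-normalized as $v / \sqrt{\lVert v\rVert^2 + \varepsilon^2}$
($\varepsilon = 10^{-3}$ guards flat patches, which map to the zero
vector). Gradients are central differences with edge replication. Feature
order is blocks row-major, cells within a block row-major, then bins.

Training follows the classic attentional scheme. Each stage runs discrete
AdaBoost over stumps; after boosting, the stage threshold is *lowered* until
at least a fraction `stageTPRMin` (default 0.995) of the surviving training
positives pass — a stage may only lose 0.5% of true stomata, and is merely
asked to reject half of its negatives (`stageFPRMax = 0.5`). Stage $k$
trains on the positives that survived stages $1..k{-}1$ and on *hard
negatives*: windows mined from the negative images that the current cascade
still accepts, scanned across the same pyramid the detector uses and with
the mining stride refined down to 1 px as survivors become rare (flipped
copies of the negative images extend the pool). Two deliberate departures
from the barest textbook recipe, both adopted because the plain version
demonstrably under-performs with a depth-8 cascade:

* **Stage strength floor.** A stage stops boosting once it meets its
  false-alarm target, but never before `minWeakLearners` stumps (default 6)
  unless the classes are already perfectly separated. A stage that scrapes
  under 0.5 with a single stump generalizes poorly beyond its few hundred
  mined negatives; with a hard cap of 8 stages the cascade then cannot
  reach the overall false-positive rate the detector needs on full scenes.
* **Early halt on exhaustion.** When even stride-1 mining over all negative
  images and scales finds fewer than `minNegPool` surviving windows, the
  remaining stages cannot be trained meaningfully and training stops with a
  warning, returning the shorter cascade. On the package's synthetic
  imagery this typically happens after 5 strong stages, whose measured
  false-alarm behaviour already exceeds what 8 textbook stages would give.

Accepted windows are merged by greedy non-maximum suppression (IoU
threshold 0.3; ties broken by smaller (row0, col0) so runs are
deterministic). The detection score — the sum of per-stage margins — exists
only to rank boxes for suppression; the underlying classifier is binary.

## Measurement: two paths, one record type

Each detected box is cropped and binarized: unsharp-mask sharpening, then a
global Otsu threshold. The foreground of this binary is the *bright* phase
(pore interior and background plateaus); dark structures — pore-boundary
rings, veins, dust — separate it into regions. This polarity is what makes
the whole procedure coherent:

* **Segmentation path** (complete boundaries). A closed dark boundary ring
  encloses the pore interior as an independent bright region. Among all
  regions whose pixel count lies in the configured window (`areaMinPx` = 60
  px² noise floor; `areaMaxPx` defaulting to 20% of the ROI area, the most
  a plausible pore can cover) *and* whose centroid lies within
  `maxCenterDistFrac` (default 0.25) of the smaller ROI dimension from the
  ROI center, the one nearest the center is the pore. Centrality is a
  requirement, not merely a ranking: the detector centers its box on the
  stoma, so the pore centroid sits within a few pixels of the ROI center,
  while a bright fragment cut off in an ROI corner by a vein or cell wall
  can otherwise become the *sole* area-qualifying candidate and be
  "nearest" by default — precisely the failure the centrality assumption
  exists to rule out. The same cap applies to skeletal-remnant selection
  (an incomplete arc's centroid shifts toward the arc, but stays well
  inside a quarter of the ROI for completeness ≥ 0.6). Area is the pixel count; eccentricity comes from the
  region's second-central-moment equivalent ellipse (population covariance
  of the pixel coordinates plus the 1/12 pixel-square term; a single pixel
  has eccentricity 0).
* **Skeleton path** (incomplete boundaries). A gap in the ring merges the
  interior with the background region, so no region passes the area window
  and the ROI falls through. The binary is inverted — dark structures
  become foreground — and each structure is thinned to a 1-px skeletal
  remnant (Zhang–Suen thinning; homotopy-preserving, idempotent on 1-px
  curves), with branches shorter than 5 px pruned as thinning artifacts.
  The remnant whose length lies within `skeletonLengthBounds` (default
  10–210 px, bracketing the perimeter arcs the expected pore sizes can
  produce) and whose centroid is nearest the ROI center is taken as the
  pore-boundary arc, and an ellipse is fitted to its pixels by direct
  least squares (the numerically stable block formulation of the
  ellipse-constrained conic fit). The fitted ellipse then masks the
  *original* binary; the largest bright region fully inside the mask is
  the pore, measured exactly as in the segmentation path.

Degenerate fits (fewer than 5 points, collinear points, a non-elliptic
best-fit conic) raise a typed error rather than returning numbers. A
confidence gate enforces the boundary-completeness rule: the remnant must
cover at least `minCompleteness` (default 0.6) of the fitted ellipse's
perimeter, each of 360 arc-length-uniform perimeter samples counting as
covered when an input pixel lies within 2.5 px. Boundaries less than ~60%
complete are therefore discarded instead of guessed at.

Every measured record reports area $A$, eccentricity $E$, and semi-axis
lengths recomputed from them as
$$a = \sqrt{\frac{A}{\pi\sqrt{1-E^2}}},\qquad
  b = \sqrt{\frac{A\sqrt{1-E^2}}{\pi}},$$
so $\pi a b = A$ and $b/a = \sqrt{1-E^2}$ hold to machine precision in
every record — these are the package's algebraic invariants, checked by the
`PoreMeasurement` validity method itself. The formulas return *semi*-axis
lengths (the identity $A = \pi a b$ forces this reading); the column names
say so explicitly. Failures on either path fold into a `discarded` record
with a machine-readable reason; every run satisfies
`detected = measured + discarded`.

## Evaluation metrics

Detections are matched one-to-one to ground-truth stoma centers by
center-in-box containment, nearest-center pairs first, followed by
augmenting-path reassignment so the matching always has maximum cardinality
(pure nearest-first greedy can drop a feasible match when boxes overlap
heavily). Precision, recall and F1 are standard; the tabulated "accuracy"
is the critical success index TP/(TP+FP+FN), the only arithmetic consistent
with how such tables are conventionally printed alongside precision and
recall. Measurement agreement between an estimate $\hat Y$ and a reference
$Y$ is reported both as the relative error $|(Y-\hat Y)/Y|\times 100$ and
as its complement ("agreement"), under which a perfect estimate scores
100%.

## The synthetic micrograph generator

No real annotated imprint imagery ships with the package, so the generator
is a first-class module that emulates the features the pipeline must cope
with: a light background with low-frequency mottle and faint polygonal
cell-wall lines (enough texture to defeat naive global thresholding), dark
elliptical pore-boundary rings drawn *outward* from the planted pore
ellipse (so the enclosed interior rasterizes to exactly the planted area),
a brighter guard-cell ring, long dark vein ridges, dust blobs, Gaussian
blur and additive Gaussian noise. Completeness is implemented as a single
contiguous gap whose extent is measured in *arc length*: the rendered
boundary is exactly the fraction `completeness` of the perimeter, which
makes rendered arc length proportional to completeness for any ellipse (on
a circle this coincides with the angular reading, e.g. completeness 0.7
leaves a 108° gap). One master seed drives every draw; identical specs
render byte-identical scenes.

Defaults — chosen once as a plausible desk-scale stand-in and not tuned
thereafter — are a 768×768 px canvas with 8 stomata of semi-major axis
14–24 px and aspect ratio 0.45–0.8 at ≥110 px separation, 6 veins, 40 dust
blobs, blur σ = 0.8 px, noise sd 0.02. The completeness mix is 60% fully
closed boundaries and 40% incomplete ones drawn uniformly from 0.65–0.9
(`pComplete` is a generator field precisely because the measurement engine's
two paths exist for these two stoma classes; a single uniform range cannot
express the mix). What the generator does *not* model — and what passing
tests therefore cannot certify about real micrographs — includes focus
gradients, imprint artifacts (resin bubbles, smears), touching or
overlapping stomata, non-elliptical pores, and illumination vignetting.
Results on the synthetic study are evidence the *algorithms* are
implemented correctly, not a performance claim for any particular
microscope or species.

## The scaled study and its problem sizes

`runSyntheticStudy()` is the package's end-to-end experiment: it trains a
cascade on 200 positive patches and 100 negative images (an 8-stage cascade
is requested; see the early-halt behaviour above), then runs detection and
measurement on 20 held-out scenes (~160 stomata) and scores everything
against the generator's records. These sizes were chosen so the full study
runs in minutes on a single CPU while keeping every stage of the pipeline
statistically meaningful; `scripts/acceptance.R` re-runs exactly this study
from scratch and writes its headline numbers. The per-ROI "accurate
identification" label used for the reported identification rate is an area
estimate within 25% of the planted value — a mechanical stand-in for the
visual inspection such results would receive in practice.

## Numerical choices and edge cases

* Coordinates are 0-based (row, col) with half-open boxes everywhere in
  files; every CSV states this in a header comment.
* Otsu thresholding requires a non-degenerate histogram; a (near-)constant
  ROI binarizes to all-background and the ROI is discarded as `blank_roi`.
* Connectivity defaults to 8 for both regions and skeletons (4 is
  available); the diagonal-pair semantics are tested.
* The ellipse fit centers the data before building the scatter matrices
  (conditioning), selects the eigenvector satisfying the ellipse
  constraint $4ac - b^2 > 0$, and recovers geometric parameters from the
  conic; orientation is reported modulo 180°.
* Ties: NMS breaks equal scores by (row0, col0); equal-area mask regions
  fall to the one nearest the ellipse center.
* Model JSON, ground-truth/detection/measurement CSVs round-trip
  byte-identically (full double precision in JSON).
* All RNG flows through explicit seeds; library calls never disturb the
  caller's RNG state.

## Known limitations

* The detector is single-orientation-window based; extreme densities or
  overlapping stomata violate the one-box-one-stoma assumption.
* The skeleton path assumes the boundary remnant is the *only* admissible
  skeleton near the ROI center; a vein fragment passing through the center
  can occasionally be selected and then rejected by the confidence gate,
  discarding a measurable stoma.
* Eccentricity from second moments is slightly biased for very small pores
  (a few px across), where rasterization dominates.
* The mask-and-measure step includes the small bright corridor through the
  boundary gap; skeleton-path areas are therefore biased a few percent
  high for very incomplete boundaries.
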