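---
title: "Lumen volumetrics and image-feature profiling of 3D microtissues"
author: "microlumen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lumen volumetrics and image-feature profiling of 3D microtissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microlumen)
```

# Scope

Estrogen-responsive MCF7 microtissues grown in non-adhesive hydrogels form
glandular lumina: fluid-filled cavities ringed by an F-actin-bright wall.
Two quantitative readouts of estrogenic response are implemented here:

1. **Lumen volumetrics** — identify luminal voids in two-channel
   (Hoechst-stained nuclei + rhodamine-phalloidin-stained actin) z-stacks,
   reconstruct them in 3D and report per-microtissue lumen counts and
   volumes.
2. **Phenotypic profiling** — normalize a samples × features image-feature
   matrix, select dose-differential features by OPLS-DA VIP, and quantify
   class separation with a random forest and multi-class ROC summaries.

Both halves are exercised end to end on seeded synthetic data with exact
ground truth, so every stage of the pipeline has an oracle.

# The lumen pipeline

## Per-slice processing

Each z-slice of the actin channel is binarized (Otsu's threshold on a
256-level histogram by default; a fixed raw-intensity threshold is
available through `AnalysisConfig(binarizeMethod = "fixed")`). Luminal
voids share the colour of the background, so candidates are found by
**morphological closing** of the foreground followed by connected-component
analysis of the complement:

* closing uses a Euclidean disk of radius $r$ µm, converted to pixels by
  round-half-up with a 1 px floor. The structuring element is exactly
  $\{(dy,dx): dy^2+dx^2 \le r^2\}$, realized through an exact
  squared Euclidean distance transform (separable lower-envelope
  algorithm, compiled code). The image is treated as embedded in an
  infinite background, so closing cannot manufacture artifacts at the
  frame edge;
* void components use 4-connectivity and foreground is closed with
  8-connected semantics implicitly (a diagonal one-pixel channel does not
  leak a void);
* the single largest void component — the background — is discarded. A
  tie is broken toward the component containing the image corner, then the
  lowest label.

A wall with a gap lets its void leak into the surrounding background, so a
single small disk misses it. The schedule therefore repeats closing with
**gradually increasing disks** — by default 6 µm initial radius, 5 µm
increments, 8 iterations (radii 6–41 µm) — and superimposes all detected
void masks by pixelwise union before relabelling. Because closing with a
larger disk never *enlarges* a surviving void, the union keeps each
candidate at its largest detected form; each candidate records the
earliest iteration at which any of its pixels appeared. Two caveats,
both deliberately reproduced and tested:

* a disk comparable to a void's own radius fills the void outright
  (the reason the schedule starts small);
* sealing a gap of width $w$ through a wall of thickness $t$ requires
  roughly $r \gtrsim w^2/(4t) + t/4$, not $w/2$ — thin-walled gaps need
  disproportionately large disks.

## Classification

Candidates are cropped into fixed-size two-channel patches (dilated by
4 µm, tight-cropped, zero-padded to square, resized to 32 px, per-channel
min-max normalized; nuclei and actin are stacked as separate channels
rather than blended). The classifier interface is pluggable:

* the shipped default scores nine engineered descriptors (void area
  fraction, border contact, extent, eccentricity, actin rim contrast,
  bright-rim fraction, interior actin/nuclei means, actin sd) with a
  seeded random forest — CPU-trainable in seconds on the synthetic
  training set, deterministic given its seed;
* any callable model (e.g. a convolutional network wrapper) can stand
  behind the same interface via `kind = "callable"`;
* `oracleClassifier()` scores candidates by overlap with a ground-truth
  label volume, isolating geometry errors from classifier errors in
  tests.

The decision threshold defaults to 0.5 and is configurable.

## Grouping and 3D reconstruction

"True" 2D lumens are grouped across slices: two candidates link when
their bounding boxes overlap in xy (closed rectangles — edge contact
counts, which keeps the rule parameter-free) and their slice distance is
at most `gapTolerance + 1`. Groups are connected components of the link
graph, split at any z-gap exceeding `gapTolerance`. The default
`gapTolerance = 0` splits at any missing slice, because a vertical gap
most probably separates vertically stacked lumens.

Each group is reconstructed as an **alpha shape** of its boundary point
cloud. Because no 3D Delaunay machinery is available in this stack, the
package implements the *grid alpha hull*: the alpha hull of a point set
equals the complement of the union of all empty alpha-balls, which is
exactly the morphological closing of the set by a ball of radius alpha.
Concretely:

1. member masks are stacked into a voxel solid on the native anisotropic
   grid (pixel size in xy, z-step in z);
2. the solid's 6-connected boundary voxels form the cloud. The first and
   last slice masks are kept whole — they are the end caps of the
   surface. (With in-plane rims alone the surface is an open tube; balls
   roll in through the ends and the hull collapses — on an r = 10 µm test
   sphere this costs about half the volume.);
3. the cloud is closed with a Euclidean ball of radius alpha (exact
   anisotropic EDT, physical units), interior cavities are filled, and
   volume/surface are integrated from the voxelization
   (µm³; exposed-face µm² — a face-counting estimate that overstates
   smooth-surface area by a known ≈1.5 bend factor but obeys similarity
   scaling, which is what downstream comparisons use).

**Alpha policy.** The source protocol never states its alpha. The default
is the *critical alpha*: the smallest alpha (bisected to 0.25 µm) whose
closed set is a single connected component containing all points; the
value actually used is recorded in every `Lumen3D`. A fixed alpha can be
forced via `alphaPolicy = "fixed"`. **Single-slice groups** are coplanar,
where any alpha shape has zero volume; they use the extrusion convention
volume = mask area × z-step instead of being dropped silently.

Voxelized spheres of radius 10–30 µm at 1 µm pixels and the 5 µm z-step
reconstruct within 5% of $\tfrac43\pi r^3$ (the test suite asserts the
15% contract); volumes at z-steps 5 vs 2.5 µm agree within 10%, and
doubling all coordinates multiplies volume by 8 and surface by 4 within
mesh tolerance.

## Nuclear counting

`countNuclei()` is a generic counterpart of instrument nuclei counting
protocols (the vendor pipeline is proprietary): maximum projection of the
nuclei channel, mild Gaussian smoothing (1.5 µm — heavier smoothing fuses
neighbouring nuclei into blobs whose distance map the watershed cannot
split), Otsu threshold,
distance-transform watershed, then filtering by an area window
(10–500 µm²) and a minimum centroid separation (4 µm, merged by single
linkage). On synthetic stacks whose generator guarantees non-overlapping
projections the count is exact.

# The profiling workflow

Feature tables are `FeatureTable` objects — `SummarizedExperiment`s with
features × samples in the assay and a mandatory `group` column — built
from CSV (`readFeatureTable()`) or the generator.

* **Orientation features** (named with an "orientation" token) are dropped
  before analysis; they encode how a microtissue happens to lie in the
  well, not its biology.
* **Range scaling**: $(x - \bar x)/(\max x - \min x)$ per feature → mean
  0, range exactly 1. **Power scaling**: $\sqrt x$ then mean-centering
  (requires non-negative input) → mean 0. These are the two winners of the
  upstream normalization benchmark for the regrouped dose designs; the
  full 168-method search is out of scope, but `compareNormalizers()`
  ranks any registered normalizers by a downstream class-separation score
  (mean per-feature one-way-ANOVA F).
* **Regrouping** (`regroupSamples()`) pools dose levels into
  low/medium/high-style groups without touching the matrix, mirroring the
  reanalysis that made the dose classes separable.

## OPLS-DA

`fitOplsDa()` fits orthogonal PLS discriminant analysis against a centered
one-hot group encoding with **one predictive component** (the published
parameterization: `predI = 1`, 2-fold cross-validation, orthogonal count
optimized automatically). The predictive weight is the leading singular
vector of $X^\top Y$ (for two groups this is exactly the NIPALS PLS1
weight, and with zero orthogonal components the scores reduce to PLS1
scores to 1e-8 — a frozen test); orthogonal components are extracted and
deflated Trygg-style, which makes predictive and orthogonal scores
exactly orthogonal. Under `nOrtho = "auto"`, components are added while
cross-validated Q² (stratified folds, seeded) improves by more than 0.01,
capped at 10 — the convention behind "orthoI = NA" in the reference
implementation of the field.

**VIP** with one predictive component is $\sqrt{p}\,|w_j|/\lVert w\rVert$,
so $\operatorname{mean}(\mathrm{VIP}^2) = 1$ identically — asserted on
every fit. The differential-feature rule is VIP > 1.0 (the community
convention; the source protocol does not state its cutoff), configurable
in `selectDifferentialFeatures()`. `intersectFeatures()` provides the
order-stable cross-exposure intersection used to build a common feature
set.

## Random forest and multi-class ROC

`trainRfAndEvaluate()` draws a stratified 80/20 split by seed, trains a
100-tree random forest (the published `ntree`), and computes one-vs-rest
ROC on held-out class probabilities. AUC uses the rank (Mann-Whitney)
form, identical to trapezoidal integration with mid-rank ties — frozen
against an explicit curve-integration oracle. The macro-average is the
arithmetic mean of per-class AUCs; the micro-average pools all
one-vs-rest (score, label) pairs before a single AUC — the
pooled-decision convention (the probability-averaging alternative is not
implemented; the source protocol does not say which it used).

## ΔΔCt

`ddctFoldChange()` implements the Livak convention:
$\Delta Ct = Ct_{target} - Ct_{ref}$,
$\Delta\Delta Ct = \Delta Ct_{treat} - \Delta Ct_{ctrl}$, fold
$= 2^{-\Delta\Delta Ct}$. The protocol prose describes the opposite
subtraction order, which would invert all fold changes; since the raw Ct
values are unavailable the standard convention is the default and
`flipSign = TRUE` provides the other reading.

# Synthetic data: what it emulates, and what it does not

`generateMicrotissueStack()` renders a spherical microtissue (bright
cortical shell, dim cytoplasm) containing ellipsoidal voids with bright
walls, plus Gaussian-blob nuclei and additive Gaussian noise. Defaults
describe a realistic 20× acquisition: 256 × 256 px at 1 µm/px, 25 slices
at the instrument's 5 µm z-step, a 55 µm tissue, 40 nuclei of 4 µm
radius, 3 µm walls, 2% noise. Wall gaps are a missing angular sector
parameterized by chord width in µm on every slice the lumen spans —
precisely the defect the closing schedule must heal. Nucleus placement
rejects candidates closer than 2.2 radii in the xy projection, which is
what makes projection-based counting exact. All randomness flows from one
seed; ground-truth labels are assigned before noise, so `GroundTruth` is
invariant to the noise level (tested).

Deliberately not emulated: optics (PSF, attenuation with depth,
photobleaching), multi-microtissue fields, non-ellipsoidal or branched
lumina, textured cytoplasm. Passing tests therefore demonstrate that the
geometry, schedule, grouping and volumetrics are correct under the stated
imaging model — not that the shipped default classifier matches a
transfer-learned network on real micrographs. On real data the classifier
is the component to re-train (the interface accepts any callable); the
geometric stages carry over unchanged.

`generateFeatureTable()` draws i.i.d. Gaussian features and shifts planted
differential features by a per-group effect profile (monotone by default,
alternating in sign across features, as real dose-responsive features move
in both directions), with a configurable fraction of orientation-named
dummies. `generateCandidatePatches()` emulates a marked training set:
enclosed dark voids with bright rims versus border notches and rimless
dark blobs.

# Numerical choices and edge cases

* µm→px conversions: round half up, floor 1 px (pinned so bounding boxes
  and schedules are reproducible across calibrations).
* Otsu on a constant slice: all-background mask, with a message.
* Erosion treats outside-of-frame as background; closing embeds the frame
  in an infinite background (both conventions frozen against offset-based
  brute-force oracles).
* Candidates below 10 px² are dropped (`minCandidateArea`); the
  classifier absorbs most false positives, the floor only bounds compute.
* Serialized outputs (JSON manifests, results) use 0-based (z, y, x)
  indices and half-open boxes; the in-memory API is 1-based R convention.
  Physical coordinate = 0-based index × calibration either way.
* Constant features cannot be range-scaled and are dropped with a
  warning; negative input to power scaling is an error naming the
  feature.
* A test split missing a class is re-drawn with a warning (possible only
  for tiny groups).

# Problem sizes

The test and acceptance workloads are sized for a laptop-class single
core: 21–25-slice stacks of 192–256 px, 20-stack recovery sweeps,
1600-patch classifier benchmarks, 80 × 100 profiling tables over 20
seeds. The full suite runs in a few minutes; `scripts/acceptance.R`
recomputes the headline quantities from scratch in under five.

# Known limitations

* Surface areas use exposed-face counting (upward-biased on smooth
  surfaces); volumes are the calibrated quantity.
* The critical-alpha search assumes the lumen's boundary cloud can be
  sealed by some alpha ≤ 64 × max(voxel spacing); pathological clouds
  raise an error rather than returning a silent zero.
* OPLS-DA uses a single predictive component by design; strongly
  multi-modal group structures are better served by the RF stage.
* The lumen walls of touching lumina can merge into one candidate; the
  pipeline reports what the closing schedule separates.
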