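---
title: "Methods: circle-likeness and hyperintensity tests for aortic disease on CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circle-likeness and hyperintensity tests for aortic disease on CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortacad)
```

## The diagnostic model

On axial contrast-enhanced CT, the healthy aortic lumen is a bright,
near-circular disk in a known Hounsfield-unit window (default 200–500
HU). Two disease signs are modeled:

* **Aortic dissection.** Blood entering the media creates a second
  (false) lumen; the intimal flap splits the cross-section and the
  pressure difference distorts both sub-lumens. The observable sign is a
  *non-circular* aortic cross-section.
* **Penetrating aortic ulcer (PAU).** An ulcerated plaque traps contrast
  medium in a pouch at the wall, and the causative calcification is
  itself radiodense. The observable sign is a cluster of pixels *above*
  the lumen window inside the aortic boundary.

The pipeline therefore runs three stages per slice: (1) segmentation —
inclusive HU-window thresholding, 8-connected component labeling, and
seeded nearest-centroid tracking of the ascending and descending aorta;
(2) the circle-likeness classifier; (3) the PAU detector.

### The circle-likeness score

The Sobel masks (`[[-1,0,1],[-2,0,2],[-1,0,1]]` and its transpose, edge
replication at borders) give per-pixel gradients and the gradient angle
`G_theta = atan2(G_y, G_x)` in degrees `[0, 360)`. For each aortic
object the centroid is the arithmetic mean of its pixel positions, and a
boundary pixel pair `(P_1, P_2)` is *satisfying* when all of:

1. `|G_theta1 − G_theta2|` is within `angle_tol_deg` of 180° (circular
   difference);
2. `G_theta1` matches the angle of the chord `P_1 P_2` modulo 180°,
   within `angle_tol_deg`;
3. the perpendicular distance from the centroid to the chord's infinite
   line is at most `line_tol_px` (inclusive).

For a circle with a radial gradient field, every boundary pixel has a
satisfying diametric partner. For an eccentric shape the boundary normal
and the central chord diverge (for a 3:1 ellipse by up to ~53°), so
condition 2 fails over most of the boundary. The score is the fraction
of boundary pixels belonging to at least one satisfying pair — each
pixel counted once however many partners it has — and an object whose
score *reaches* the threshold (inclusive) is `circle_like`, otherwise a
`dissection_candidate`. The pair search is a full O(B²) scan; aortic
boundaries are at most a few hundred pixels, so no spatial index is
warranted and the implementation can be checked verbatim against a
brute-force enumerator (the test suite does exactly that).

### The PAU detector

Pixels with `HU > upper` (strict, so the lumen and PAU masks partition
intensities) that lie in the *filled interior* of the aortic object are
grouped 8-connectedly; components of at least `min_pau_px` pixels become
candidates, reported with their peak HU. "Inside the boundary" is
implemented as morphological hole filling of the object mask because PAU
and calcification pixels are, by construction, carved out of the lumen
mask by the threshold — they reappear as closed holes or wall-adjacent
notches in the segmented object.

### Evaluation

The unit of evaluation is the aortic object per slice, ascending and
descending counted separately. Positive means "flagged as a disease
candidate"; sensitivity is `TP/(TP+FN)`, specificity `TN/(TN+FP)`, both
reported to 4 decimals (round half to even — with the published
per-region counts this reproduces 83/101 → 0.8218, 534/539 → 0.9907,
239/315 → 0.7587 and 323/333 → 0.9700, which the acceptance suite
asserts). Region tables carry an "all" row defined as the sum of the
region rows.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `hu_range` | HU | 200–500 | average window of contrast-enhanced aortic blood; both bounds inclusive for the lumen |
| `threshold` | fraction | 0.60 | decision threshold on the boundary-pair score; inclusive ("reaches") |
| `angle_tol_deg` | degrees | 10 | exact angle equalities are measure-zero on a grid; 10° absorbs Sobel discretization error on rasterized circles while still failing an eccentric boundary |
| `line_tol_px` | pixels | 2 | centroid-chord distance tolerance; of the order of one boundary pixel's quantization |
| `min_object_px` | pixels | 50 | rejects contrast-filled vessels much smaller than the aorta |
| `min_pau_px` | pixels | 3 | suppresses single-pixel artifact hits slightly above the window — the dominant false-positive mode |
| `continuity_limit_px` | pixels | 20 | maximum slice-to-slice centroid displacement during tracking |

All of these are config-exposed (`default_config()`, YAML config file);
the defaults are the package's standard operating point and are the
values used throughout the tests.

## The phantom: what it emulates, and what a green test establishes

`phantom_spec()` states a synthetic world: soft-tissue background at
40 HU, lumen disk at 350 HU (mid-window), PAU blobs at 800 HU, one
additive Gaussian noise source (`noise_sd`, default 10 HU) applied to
every pixel, per-slice RNG streams derived from one seed so output is
byte-reproducible. The constructor validates 3-sigma class separation
(lumen ± 3σ inside the window, background + 3σ below it, PAU − 3σ above
it) and refuses inconsistent settings; `noise_sd = 0` is the
deterministic noise-free case. Dissection is modeled two ways because
both occur clinically: a dark intimal-flap band splitting the disk into
two distorted sub-lumens (detectable), and a shape change to an ellipse
of axis ratio ≥ 2 at equal area (detectable); dissections that *preserve*
a circular outline are deliberately not generated — the classifier is
blind to them by design. PAU blobs are planted fully inside the disk,
1–2 px from the wall, so they become closed holes after thresholding.

The phantom does **not** model beam hardening, streak artifacts,
partial-volume averaging, textured tissue, neighboring vessels touching
the aorta, or the aortic arch. A green phantom test therefore
establishes algorithmic correctness (masks recovered exactly, scores
matching the brute-force oracle, planted lesions found) — not clinical
performance; the published per-patient figures enter only through the
evaluation module's arithmetic on their printed counts.

## Numerical choices

* **Coordinates.** 0-based `(row, col)` everywhere; x ↦ col, y ↦ row,
  row increases downward. One stated convention prevents
  mirrored-gradient bugs; the source imaging literature states neither
  its pixel nor its angle convention, so these are declared, not
  inferred.
* **Gradient angle.** The classical one-argument `arctan(G_y/G_x)` is
  quadrant-ambiguous and cannot express the 180° opposition that
  condition 1 requires; the two-argument `atan2` is used. Pixels with
  `G_x = G_y = 0` carry an undefined flag (`NA`) and never participate
  in pair conditions — any numeric angle there would be arbitrary.
* **Chord angle modulo 180°.** A chord is undirected while a gradient is
  directed; gradient polarity (into vs out of the lumen) depends on
  whether the lumen is brighter than its surroundings and is already
  captured by condition 1, so condition 2 compares modulo 180°.
* **Any-partner pairing.** Whether a boundary pixel may pair only with
  its diametric opposite or with any other boundary pixel is left open
  in the method's statement; the any-partner interpretation is used, and
  conditions 1–3 jointly confine admissible partners to a near-diametric
  arc anyway.
* **Connectivity.** Objects are 8-connected, the boundary is defined by
  4-connectivity to the exterior — the standard complementary pairing
  that avoids topological paradoxes. Hole filling floods the complement
  4-connectedly from the border.
* **Inclusive comparisons.** Lumen window inclusive at both ends, PAU
  strictly above `upper` (the two partition intensities); score
  threshold inclusive; centroid-line tolerance inclusive.
* **Tie-breaks and degenerate inputs.** Tracking picks the minimum
  centroid distance (`which.min`, first on exact ties in candidate scan
  order); objects with fewer than 8 boundary pixels are degenerate for
  the circle test and raise an error (the pipeline records them as
  `degenerate` rather than guessing); a vanished vessel produces a gap
  record and tracking resumes from the last linked centroid.
* **Display rounding.** Round half to even at 4 decimals, matching the
  reproduced summary statistics above.

## Design choices where the design was open

* The upstream segmentation method this package replaces (morphological
  operators plus an arch torus criterion) is not published in usable
  detail; HU thresholding + connected components + seeded
  nearest-centroid tracking preserves its stated inputs (DICOM-style
  slice stack, HU window, two seed positions) and outputs (per-slice
  labeled aortic objects). The diagnosis stages only need a faithful
  lumen mask.
* No R DICOM reader is available in the supported dependency set, so
  slice I/O uses plain headerless CSV arrays (one file per slice,
  index in the filename) plus a truth CSV; the in-memory types keep a
  `pixel_spacing_mm` slot so a DICOM front end can be added without
  touching the pipeline.
* Connected-component labeling is delegated to `igraph` components on
  the 8-neighbor pixel graph; the Sobel convolution, hole filling and
  the entire circle test are implemented here (they are the package's
  substance, and no image-processing package is assumed).
* The phantom's "mean and spread" intensity model is simplified to class
  means plus a single global noise SD; separate per-class texture SDs
  added nothing testable and would have doubled the parameter surface.
  The 3-sigma validation margins play the role of the spreads.

## Known limitations

* Dissections that keep a circular outline (shrinkage, visible intimal
  flap within a round lumen) are not detected — the dominant
  false-negative mode of the shape test.
* PAU with intensity inside the lumen window is invisible to the
  hyperintensity test — its dominant false-negative mode.
* A PAU notch that opens the boundary outward is not a closed hole and
  survives only if its pixels still fall inside the filled outer
  contour.
* The aortic arch is excluded (its cross-section needs multiplanar
  reconstruction), as are calcification-vs-pouch discrimination, ROC
  analysis across thresholds, and physically realistic CT simulation.
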