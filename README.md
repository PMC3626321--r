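# aortacad

Computer-aided detection of aortic disease on axial contrast-enhanced CT
slices, for radiologists and imaging researchers who need to triage large
slice stacks: the package removes innocuous images and highlights slices
with potential signs of **aortic dissection** (an abnormally shaped aortic
cross-section) or **penetrating aortic ulcer** (PAU; hyperintense,
contrast-filled pouches at the aortic wall). A synthetic phantom generator
with ground truth makes every stage testable without patient data.

## The method

The contrast-enhanced aortic lumen occupies a known Hounsfield-unit
window, by default **200–500 HU**. Each slice is thresholded to that
window (inclusive), 8-connected components are labeled, and the ascending
and descending aorta are tracked slice to slice from operator-supplied
seed positions by nearest-centroid linking.

**Dissection test (circle likeness).** The Sobel operator gives per-pixel
gradients `G_x`, `G_y` and the gradient angle
`G_theta = atan2(G_y, G_x)`. For an aortic object with centroid
`(C_x, C_y)` (the mean of its pixel positions), a boundary pixel pair
`(P_1, P_2)` is *satisfying* when

1. the gradient angles are opposed: `|G_theta1 − G_theta2| ≈ 180°`,
2. `G_theta1` is aligned with the chord through `P_1` and `P_2`
   (modulo 180°), and
3. that chord passes through the centroid.

On a circle every diametric pair satisfies all three; on a distorted
(dissected) lumen most pairs fail condition 2 or 3. The score is the
fraction of boundary pixels belonging to at least one satisfying pair;
an object whose score reaches the **60 %** threshold is labeled
`circle_like` (healthy), otherwise `dissection_candidate`. Discrete
pixels make the exact equalities measure-zero events, so explicit
tolerances apply (defaults 10° angular, 2 px centroid-line distance).

**PAU test.** Contrast trapped in an ulcer pouch — and the calcified
plaque that causes it — exceeds the lumen window, so lumen thresholding
carves such pixels out of the segmented object as holes. Pixels with
`HU > 500` (strict) lying inside the filled interior of the aortic
boundary are grouped by connected-component labeling; components of at
least 3 px become PAU candidates and the host object is flagged.

**Evaluation.** Per aortic object and slice, with ascending and
descending aorta counted separately: sensitivity `TP/(TP+FN)` and
specificity `TN/(TN+FP)`, displayed to 4 decimals.

## Worked example

Generate a 6-slice phantom study (seeded, 10 HU noise) with two healthy
slices, one flap-split dissection, two PAU slices, and run both
pipelines:

```r
library(aortacad)
spec <- phantom_spec(n_slices = 6, noise_sd = 10, seed = 7)
labels <- c("healthy", "healthy", "dissection", "pau", "healthy", "pau")
dir <- file.path(tempdir(), "phantom")
write_phantom_dir(make_phantom_study(spec, labels), dir)

cfg <- default_config()
cfg$seeds <- list(list(row = 64, col = 64, anatomy = "descending"))
res <- run_pipeline(dir, cfg, file.path(dir, "out"))
res$report
```

```
  slice_index    anatomy n_pixels centroid_row centroid_col circle_score
1           0 descending     1257       64.000       64.000       0.7946
2           1 descending     1257       64.000       64.000       0.7768
3           2 descending      530       73.858       64.000       0.1250
4           3 descending     1244       64.000       63.833       0.7742
5           4 descending     1257       64.000       64.000       0.7946
6           5 descending     1244       64.000       63.833       0.7581
           shape_label pau_count peak_hu
1          circle_like         0      NA
2          circle_like         0      NA
3 dissection_candidate         0      NA
4          circle_like         1     806
5          circle_like         0      NA
6          circle_like         1     810
```

Slice 2's flap-split lumen scores 0.125 — far below the 60 % threshold —
and is flagged; the two planted PAU blobs are recovered with their peak
HU. Since the phantom directory carries a truth table, confusion
summaries are computed too:

```r
res$summaries$dissection
```

```
   data_type tp fp tn fn sensitivity specificity
1        all  1  0  5  0           1           1
2 descending  1  0  5  0           1           1
```

`run_pipeline()` also writes `report.csv`, `log.txt` (all parameter
values and per-stage counts), overlay PNGs for flagged slices (boundary
in green, PAU pixels in red) and the summary CSVs to the output
directory. The same pipelines are available from the command line:

```sh
Rscript inst/cli/aortacad.R make-phantom --out phantom --seed 3
Rscript inst/cli/aortacad.R run-all --input phantom --out phantom/out
```

## Scope

Axial cross-sections of the ascending and descending aorta only. The
aortic arch (which needs multiplanar reconstruction), dissections that
preserve a circular outline (size change, intimal flap), and shape-based
PAU recognition on the boundary are out of scope; see the methods
vignette for the full limitation list.
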