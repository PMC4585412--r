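---
title: "Scoring rice leaf traits from line-scan imagery"
author: "leafScoreR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring rice leaf traits from line-scan imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafScoreR)
```

## The measurement problem

Rice plants carry on the order of a hundred blades, and traits of the
whole complement — how much green leaf area a plant has, how that area is
distributed over light, moderate and dark green, how long, wide, and
compact individual blades are — vary enough between accessions to be
useful quantitative phenotypes. Scoring them by hand (pasting clipped
blades on paper and flat-bed scanning, calliper measurements, visual
colour-chart matching) is the bottleneck of any large-scale study.

The instrument this package models feeds clipped blades on a conveyor
under a tri-linear (R/G/B) line-scan camera. `leafScoreR` implements the
downstream computation: turning the raw frame sequence of one plant (one
*task*) into a per-leaf record table and a 29-value per-plant trait
vector, plus the statistics used to validate such a device against a
reference method and to summarise a genome-wide association study (GWAS)
run on the traits.

## Optical geometry

The camera has square pixels of pitch $p$ (µm) and the optics magnify
object to sensor by $m$, so one pixel images
$r = p/1000 \times m$ mm and $r^2$ mm². With the stock calibration
(`defaultCalibration()`: $p = 14$, $m = 15.71$) that is 0.22 mm and
0.048 mm²/pixel; a 17.94 mm × 0.24 mm sensor then covers a field of view
of 281.84 mm × 3.77 mm. All areas are pixel counts times the pixel area;
geometry helpers round to the instrument's printed precision (2 decimals
for mm, 3 for mm²) while every internal conversion uses the unrounded
resolution, so rounding never cascades. The feeding-geometry helper
`minCylinderSpacing()` reproduces the design constraint that the two
cylinders flanking the scan line (diameter 30 mm) must sit more than
30 + 3.77 = 33.77 mm apart.

## Pipeline stages

1. **Channel re-registration** (`correctChannels()`). The three sensor
   lines see a moving scene at slightly different times, so the raw
   colour image has the green and blue planes displaced down the scan
   axis. Correction shifts them back up by whole line counts (the
   offsets are integers; sub-pixel registration is out of scope) and is
   strictly per frame. The rows vacated at the bottom of a frame are
   filled with green 0 / blue 255: mixing any red value with that fill
   lands on blue-to-magenta hues that no segmentation band accepts, so
   fill rows can never masquerade as leaf. The line offsets of the real
   sensor are not published; green +2 / blue +4 are simulation defaults
   carried in the calibration profile.

2. **HSL segmentation** (`rgbToHsl8()`, `bandMask()`). Pixels are
   converted to hue–saturation–lightness, each channel quantised to
   0–255 (hue as degrees × 255/360, so pure green is 85). Bands are
   inclusive axis-aligned boxes; the default green band is
   H 39–131, S 34–255, L 30–233 and yellow is H 0–38 with the same S and
   L — the fixed thresholds of the desktop-scanner reference method.
   None of the bands crosses the hue wrap, so no circular interval
   arithmetic is needed. The total leaf mask is the union of green and
   yellow. The three green classes are sub-bands that tile the green
   band's lightness range — light green-2 L 150–233, moderate green-3
   L 90–149, dark green-4 L 30–89. These class boundaries are a
   documented configuration default (the instrument's own values live in
   its internal configuration, not in public sources), chosen so the
   class bands are pairwise disjoint, contained in green, and jointly
   exhaustive — which makes the per-class areas partition the green
   area exactly.

3. **Impurity removal** (`removeImpurities()`). Dust survives colour
   thresholding; connected components smaller than `minAreaPx` (default
   50 px ≈ 2.4 mm²) are deleted. Components use 8-connectivity so thin
   diagonal leaf tips do not fragment; the class masks are computed as
   raw band masks intersected with the *cleaned* total mask, so a speck
   that happens to match a leaf colour but lies outside real leaves
   never contributes to class areas.

4. **Mosaicking** (`stitchFrames()`, `extractLeaves()`). A blade often
   spans two adjoining frames. Rather than cutting the partial blade
   from one frame and re-attaching it to the next, the frames are
   concatenated into the task canvas and components are labelled
   globally — provably the same result, and easier to verify. Because
   per-frame correction blanks the last `max(offsets)` rows of each
   frame, a blade crossing a frame boundary would be cut by that seam;
   the scoring pipeline therefore closes the stitched total mask with a
   scan-axis-only structuring element of height `2*max(offsets)+1` and
   width 1 before labelling. The element is one pixel wide so
   side-by-side blades cannot merge, and the generator keeps vertical
   clearances larger than the element, so bridging is exact in
   simulation. Components of at least `minLeafPx` (default 200 px ≈
   9.7 mm²) count as leaves; a blade touching the last row of the final
   frame is treated as complete, and fragments above the size threshold
   count as leaves.

5. **Morphometrics** (`leafLength()`, `leafWidth()`, `leafPerimeter()`,
   `leafCompactness()`, `classifyLeaf()`). Rice blades curl, so length
   is measured along the morphological skeleton (Zhang–Suen thinning):
   the longest endpoint-to-endpoint geodesic, with the path smoothed by
   a window-5 moving average to remove the staircase bias of
   8-connected chains, extended at each end by the local
   distance-transform radius so the measurement reaches the blade tips.
   Width is twice the maximum inscribed radius along the skeleton minus
   half a pixel (the distance transform measures to background pixel
   centres, which biases the raw doubling by +0.5 px on average).
   The perimeter is the closed polygon through the traced contour pixel
   centres after a window-3 circular moving average: the raw chain with
   √2 diagonals overestimates a digital disc of radius 50 by about 5%,
   while the smoothed polygon is within 1% on the disc and within 3% on
   a thin 100 × 10 rectangle. Compactness is the isoperimetric quotient
   $4\pi A / P^2$ (1 for a disc), the standard bounded shape statistic;
   the instrument's own formula is not published, so this choice is
   declared rather than claimed. Each leaf's colour class is the argmax
   of its green-2/3/4 (and yellow) areas, ties breaking towards the
   darker class; a leaf with no class pixels is `"unclassified"`.

6. **Trait aggregation** (`aggregateTraits()`). The 29 per-plant traits
   are 6 size traits (LN, TLA, GLA, ALA, MLA, LASD), 7 colour traits
   (GLA2/3/4, GLAR2/3/4, GLCC) and 16 shape traits (average, maximum
   and SD of length, width, perimeter and compactness, plus ALWR, MLWR,
   APAR, MPAR). The authoritative trait table is not public; this
   reconstruction covers every trait symbol that appears in public
   sources and fills the remainder by the avg/max/SD symmetry, and the
   names are exposed through `traitNames()` so a corrected list can be
   swapped in. Averages are arithmetic means over leaves, SDs are
   population SDs (divide by $n$), `GLAR_k = GLA_k / GLA` (missing when
   GLA is zero), and `GLCC = (2\,GLA_2 + 3\,GLA_3 + 4\,GLA_4)/GLA` — an
   area-weighted mean of the colour-chart class indices, i.e. a
   monotone greenness score. `APAR = ALP/ALA`; `MPAR` is the maximum
   over leaves of each leaf's perimeter-to-area ratio (the alternative
   MLP/MLA reading is not used). For near-rectangular blades
   `aparRectangular()` gives the closed form
   $APAR = 2/ALW + 2/ALL$ and its thin-blade limit $2/ALW$.

## The synthetic scanner

Validation needs imagery whose truth is known *independently of the
pipeline*. `samplePlant()` draws leaves as parametric shapes —
rectangles (straight-blade limit), tapered ellipses, and constant-width
blades swept along circular arcs (curvature 0–1 maps to 0–90° of arc) —
with analytic length, width, area and perimeter. Dimensions are snapped
to whole pixels so rectangle truth is exact under rasterisation. Default
blade sizes are 120–280 mm × 8–14 mm, a realistic span for rice;
unit tests use 25–60 mm blades on small canvases purely to keep
suites fast, and state so explicitly where they do.

Leaves are shelf-packed without overlap (the physical feeder separates
blades, so overlap handling is deliberately out of scope) on a canvas
one frame wide; when the canvas exceeds one frame height the packing is
nudged so at least one blade straddles a frame boundary, exercising the
mosaicking path. Each leaf's HSL centre is sampled at least 11 counts
inside its class band and per-pixel jitter (±3) is clipped 8 counts
inside the band; 8-bit RGB quantisation can perturb a round-tripped HSL
value by up to about 7 saturation counts at the lightness extremes, so
these margins guarantee that *every* rendered leaf pixel still
segments into its true band — which is what makes exact mask-level
oracles possible. Dust is modelled as 1–20 px random-walk specks, half
coloured uniformly at random and half drawn inside leaf colour bands,
placed on background clear of leaves. Everything is deterministic given
the task seed: identical seeds give bit-identical rasters.

What the generator does **not** emulate: illumination gradients and
sensor noise (undocumented for the real device), venation and texture,
specular highlights, overlapping or touching blades, and sub-pixel
channel mis-registration. Pipeline accuracy on synthetic scans is
therefore an upper bound, not a field calibration; the accuracy
statistics (`mape()`, `apeSD()`, `rSquared()`, `discriminationError()`)
exist precisely so a user with reference measurements can repeat the
validation on real material.

## Numerical choices and degenerate inputs

* 8-connectivity everywhere components are labelled (the base labeller
  is 4-connected; diagonally touching labels are merged afterwards).
* Masks are padded with one background pixel before the distance
  transform so components that fill their bounding box (rectangles) see
  background on all sides.
* A mask whose skeleton collapses to a point (disc- or square-like)
  falls back to `2*max(dt) - 0.5` px — its inscribed diameter — for
  length, so length equals width on squares by construction. The
  skeleton of a square is its diagonal medial axis, so near-isotropic
  shapes are not meaningful targets for a blade-length estimator;
  accuracy claims are restricted to elongated shapes.
* Single-pixel components measure one pixel in length and width;
  a zero perimeter is impossible by construction and rejected in
  `leafCompactness()`.
* Length recovery is within 2% on rectangles and 3% on quarter-circle
  blades of realistic width; short blades that are simultaneously wide
  and strongly curved can read a few per cent long because the thinning
  skeleton reaches into the corners of the radial end caps. Tapered
  ellipses read a few per cent short (the skeleton ends where the tip
  narrows to the pixel scale). Width is exact to ±0.5 px, area is exact
  on the mask, perimeter is within 4% on thin rectangles.
* Clumping ties (equal smallest p in a locus) resolve to the smaller
  position; locus bounds are the member extremes, not padded intervals.
  A gap of exactly the threshold starts a new locus (the rule is
  "closer than", inclusive bounds are "at least").
* Thresholds and filters use inclusive comparisons (MAF ≥ 0.05,
  MAC ≥ 6).
* R² is the squared Pearson correlation of reference versus test — the
  conventional statistic for method-against-method scatter — not the
  regression-through-origin variant; both can be derived from the pair
  vectors if needed. APE spread is the population SD of per-sample
  absolute per cent errors.

## Problem sizes used in validation

The shipped suites validate: geometry arithmetic against the printed
instrument constants; mask-identity of stitched-frame extraction versus
unsplit extraction on 100 random tasks; exact distort→correct round
trips on interior rows; rectangle recovery at 2% (length, width, area)
and 4% (perimeter); end-to-end green-leaf-area error under distortion,
dust and frame cuts below 5%; zero discrimination error on a 50-leaf
single-class batch (mirroring the instrument's three 50-leaf
colour-chart batches); locus clumping against a brute-force
transitive-closure oracle on 1000 random SNP sets; and the thin-blade
APAR limit at 4%. Unit-test canvases are a few hundred pixels per side
and the discrimination batch uses the full default geometry; these sizes
are the package's validation protocol and are all regenerated in code —
no image fixtures ship with the package.

## Known limitations

* The green-class lightness boundaries, channel offsets, dust model and
  impurity thresholds are declared simulation defaults, not measured
  instrument constants; all are configuration-exposed.
* The per-leaf trait definitions (length, width, compactness) are
  principled reconstructions; a device comparison would need the
  vendor's exact definitions.
* The GWAS module summarises an existing association scan; it does not
  fit mixed models, estimate kinship, or test epistasis, and published
  locus counts cannot be reproduced without the underlying SNP tables.
* Scoring assumes separated blades; touching or overlapping leaves are
  a single component and would be measured as one.
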