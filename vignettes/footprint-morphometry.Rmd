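---
title: "Plantar footprint morphometry: models, conventions and validation"
author: "footmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plantar footprint morphometry: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footmorph)
```

## The measurement problem

Deformities of the medial longitudinal arch — pes planus (flat foot) at one
extreme, cavus foot at the other — are classically graded from the plantar
contact print: the shadow a standing foot leaves on a podoscope glass or an
inked mat. Manual grading with a caliper on paper prints is noisy and
observer-dependent, so `footmorph` computes the three standard print indices
from an RGB image automatically:

* **Staheli arch index** $Q/R$ — narrowest midfoot width over widest
  hindfoot width. Larger means flatter.
* **Chippaux–Smirak index** $100\,Q/P$ (percent) — narrowest midfoot width
  over widest forefoot width. Larger means flatter.
* **Clarke's (arch) angle** — at the medial forefoot point $t_1$, between
  the medial tangent line $T$ (from $t_1$ to the medial hindfoot point
  $f_1$) and the line $S$ from $t_1$ to the deepest point $s_1$ of the arch
  concavity. Proportional to arch height: near 0° for a fully flat print,
  above 50° for a pronounced cavus foot.

Each index is then assigned to one of five groups (1 Cavus, 2 Cavus-Normal,
3 Normal, 4 Normal-Flat, 5 Flat) using published boundary values; see
`defaultClassificationTable()`.

## Pipeline and its assumptions

`analyzeFootprint()` chains five stages. All conventions below are package
decisions where the underlying method leaves the detail open; each is
recorded here once.

**1. Colour segmentation.** The sRGB image is converted to CIELAB (D65) and
the opponent channels are encoded 8-bit offset-binary (neutral at 128, the
common byte encoding of a\*/b\*). A pixel is plantar-contact candidate when
encoded a\* > 122 **and** b\* > 131: skin tones sit well into the red and
yellow quadrant while white/grey backgrounds rest on the neutral axis and
any blue cast fails the b\* test. Luminance is ignored entirely, which is
what makes the test tolerant of uneven podoscope illumination. The AND
combination is the default because each channel alone admits large
non-skin families (the a\* test alone passes neutral grey); `combine =
"or"` is available for unusually lit setups.

**2. Dilation.** The binary mask is dilated with a 3×3 square element, 2
iterations (both configurable). The dilation exists to reconnect regions
the colour threshold fragmented, *not* to define the print outline: when
`extractFootprints()` receives the pre-dilation mask it returns, per foot,
the undilated pixels inside the selected dilated component. Widths are
therefore measured on the thresholded silhouette rather than on a outline
inflated by two pixels per side. If dilation merges the toes into the
sole, lower `dilationIterations`; there is no active toe-cutting
heuristic, toes are removed as small separate components.

**3. Component extraction.** Components use 8-connectivity throughout.
Components smaller than `minComponentFraction` (default 1%) of the image
area — toes, speckle from sensor noise — are discarded; `expectedFeet`
selects the largest one or two, and `"auto"` keeps what passes the area
test, capped at two. For two feet, results are ordered image-left first.

**4. Calibration.** The 1 cm² fiducial sticker is found as the largest
dark component (red channel < 183) in the bottom quarter of the image, and
`pixels_per_cm = sqrt(area_px)`. The search strip exists so the dark
marker can never be confused with the foot; the marker must be placed
below the heel. Without a marker the analysis either fails or, with
`allowUncalibrated = TRUE`, reports pixel units.

**5. Geometry.** The toeless print is oriented toes-up (the CLI `--toes`
flag rotates other orientations). Its bounding rows are split into three
equal bands — forefoot, midfoot, hindfoot, remainder rows to the hindfoot —
because the source method never defines the band boundaries; equal thirds
is the simplest convention that treats both feet symmetrically. Width on a
row is the pixel-centre distance `|col_inner − col_outer|` (a one-pixel row
has width 0), consistent with applying the two-point distance formula to
boundary pixel centres. Extremal-row ties are broken toward the zone's
centre row, then the smaller row index — deterministic where the method is
silent. The deepest arch point $s_1$ is identified with $q_2$, the medial
endpoint of the narrowest midfoot line: both are "the inner point of the
midfoot", and collapsing them removes one scan.

**Side detection** is intrinsic rather than positional: the medial border
is the side whose midfoot boundary deviates more from the chord joining
its extreme midfoot points. Positional rules (left half = right foot) fail
for single-foot images and mirrored camera mounts. Prints with no usable
arch cue (a fully flat print is nearly rectangular) raise a "side
ambiguous" error; callers that know the stance pass `forceSide`.

**Clarke's angle, angle convention.** The angle is computed at $t_1$ by
the law of cosines, $\arccos((S^2+T^2-F^2)/(2ST))$. A second variant
(`variant = "as_printed"`) evaluates $\arccos((T^2+F^2-S^2)/(2TF))$ — the
angle at the *hindfoot* vertex — because instrument descriptions sometimes
quote the formula in that arrangement; the textual definition (the angle
between $S$ and $T$, which meet at $t_1$) is the default and both are
tested. Note the two differ for every non-isosceles triangle.

**Classification boundaries.** Group intervals are half-open with the
lower bound inclusive for the ascending indices
((−∞,b₁), [b₁,b₂), …, [b₄,∞)); for the descending arch angle a boundary
value joins the higher-arch (smaller-numbered) group, e.g. 50° is group 1.
The Chippaux–Smirak table ranges are on the 0–1 fraction scale while the
index itself is a percentage; `classify()` divides by 100. This is easy to
get wrong when comparing against other software — check the scale first.

## The synthetic generator as reference standard

No public image set accompanies the method, so validation rests on
`generateFootprint()`: a parametric print whose ground truth is known by
construction. The toeless silhouette is the union of a forefoot ellipse, a
hindfoot ellipse and the trapezoid joining their widest chords, minus a
medial circular-segment concavity of depth `archDepthPx` — a single dial
that sweeps the flat-to-cavus continuum. Detached elliptical toes sit
above the forefoot, a dark reference square near the bottom edge, all over
a light background with optional Gaussian pixel noise; the default skin
tone sRGB(220,160,130) encodes to a\* = 146.7, b\* = 152.5, comfortably
inside the segmentation thresholds. Defaults render a left foot of 420 px
(10.5 cm at the 40 px/cm set by the default 40-px marker) on a 600×321
canvas; the odd width puts the foot axis on an integer pixel column, so a
`side = "right"` render is a pixel-perfect mirror.

Ground truth is derived from the continuous construction before
rasterisation — never by re-measuring the rendered mask — which keeps the
oracle independent of the code under test. One subtlety: the quantities
the pipeline measures are *pixel-centre* widths and grid key points, so
`trueMeasures` reports the analytically quantised widths
$\lfloor w_{med}\rfloor + \lfloor w_{lat}\rfloor$ of the continuous
profile (the exact true value of the measurand; the continuous widths are
also included as `continuousQ/R/P`), and extremal rows are selected from
those quantised offsets under the same stated tie-break rules. On clean
renders the pipeline reproduces this ground truth exactly; the tests
assert recovery within ±2 px and ±2°.

What the generator deliberately does *not* emulate: pressure-dependent
intensity gradients, soft print edges, ink bleed, illumination gradients,
perspective and lens distortion. Passing tests therefore demonstrate the
correctness of the measurement geometry and the robustness of the
segmentation to additive noise — not performance on clinical images, which
depends on capture quality.

`generateCohort()` emulates a repeated-measures precision study: subjects
drawn from a configurable mix of the five groups, five stance repeats each
by default, with between-repeat jitter in rotation (±1.2°), vertical
placement (±2 px), arch depth (sd 1.5 px) and pixel noise (sd 3) — small
perturbations representing stance-to-stance variability of a cooperative
adult. The simulated stance side is passed to the analysis (`forceSide`),
since the flattest prints under noise can have a genuinely ambiguous arch
cue. With 40 subjects × 5 repeats the cohort yields 200 samples; note that
with n = 5 the largest possible deviation is $(n-1)/\sqrt{n} \approx 1.79$
standard deviations, so the three-sigma rule cannot fail at this repeat
count — the interesting precision signal is in the one-sigma counts and
the standard deviations themselves.

## Numerical choices

* Sample (n−1) standard deviation in `sigmaRuleReport()`; at n = 5 the
  population choice would shrink σ by ~11%, so the convention matters and
  is stated. "Outside kσ" is a strict inequality.
* `clarkeAngle()` clamps cosines within 1e-8 of ±1 (flagging collinear
  key points, which genuinely occur for fully flat prints) and rejects
  larger triangle-inequality violations as degenerate.
* Coordinates are 1-based (row, col) with row 1 at the top, R's matrix
  convention; all geometry is translation-invariant so no off-by-one can
  leak into lengths or angles.
* Problem sizes in the validation suite: oracle equivalence on 200 random
  64×64 masks and 1000 random triangles; recovery and silhouette-overlap
  checks on 50 and 20 renders spanning all five groups; one full
  40-subject cohort. These sizes give stable pass/fail behaviour while
  keeping a complete run inside a few minutes on one core.

## Known limitations

* The three-zone split is a convention; methods that define zones from
  anatomical landmarks (e.g. parabola fits to the arch border) will place
  Q/R/P on slightly different rows for the same print.
* Side detection needs a visible arch cue; fully flat prints require
  `forceSide`.
* A split print (severe cavus with no midfoot contact) segments into two
  components and is rejected rather than measured; the indices are not
  defined for it (Q does not exist).
* Calibration assumes the fiducial square is flat on the glass and
  unoccluded; accuracy degrades with the square's segmentation, not with
  the foot's.

## A worked example

```{r example, eval = FALSE}
library(footmorph)

sample <- generateFootprint(FootShapeParams(archDepthPx = 88, seed = 7))
res <- analyzeFootprint(sample@image)[[1]]
res
#> FootprintAnalysis of a left foot
#>   calibration: 40.00 px/cm
#> IndexSet
#>   Staheli arch index:    0.4930
#>   Chippaux-Smirak index: 38.89 %
#>   Clarke's angle:        33.37 deg
#> ClassificationResult (1 Cavus .. 5 Flat)
#>   Staheli:         group 3 (Normal)
#>   Chippaux-Smirak: group 3 (Normal)
#>   Clarke:          group 3 (Normal)
```

All three indices classify this mid-depth arch as Normal, and the measured
values match the generator's analytic ground truth exactly on this clean
render.
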