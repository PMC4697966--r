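---
title: "Regional histomorphometry of the proximal humerus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional histomorphometry of the proximal humerus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(humerometry)
```

## The measurement problem

Osteoporotic fractures of the proximal humerus cluster in characteristic
zones, and implant anchorage depends on how much bone those zones actually
contain. On a frontal (coronal) section of the proximal humerus, the quantity
of interest for cancellous bone is BV/TV — in 2D histomorphometry, the bone
area fraction within a region, reported in percent — and for compact bone the
thickness of the subchondral plate and of the medial and lateral metaphyseal
cortex. Because humeri differ in size and shape, regions must be placed by a
reproducible geometric construction rather than by hand.

`humerometry` implements that construction and the downstream statistics on
calibrated, pre-segmented input: two aligned binary rasters (mineralized bone
and hyaline articular cartilage) plus a small annotation marking the cranial
and caudal ends of the articular cartilage. Interactive stain-based
segmentation is deliberately out of scope; the mask contract is the interface,
and a mask is something any modern segmentation tool can produce. Calibration
(mm per pixel) is always a required user input because raster sources differ.

## The landmark system

All regions and measuring points derive from five construction lines:

* **line a** — the central long axis of the humerus. By default it is fitted
  to the distal 35% of the tissue envelope (the parallel-sided shaft):
  a principal-axis seed followed by regression of the cross-axis centroid of
  slim slices on the along-axis position, iterated three times. The slice
  regression is exact for a parallel-sided shaft and, unlike a raw
  second-moment fit, does not degrade when the selected distal block is
  nearly square. An explicit two-point override is honoured when provided.
* **line b** — the chord from the cranial to the caudal end of the articular
  cartilage, taken verbatim from the annotation. It approximates the course
  of the anatomical neck; its midpoint serves as the head center.
* **line c** — perpendicular to line a through the caudal end of line b.
* **line d** — parallel to line a and tangent to the medial periosteal
  contour within the distal third of the section; ties between equally
  medial candidates resolve to the more distal one. Line d splits line c
  into a medial and a lateral segment; one third of the medial segment is
  **s1**. The medial end of the segment is the caudal cartilage end itself —
  line c passes through it by construction and the cartilage margin lies on
  the periosteal surface — so the segment is anchored at an exact annotated
  point rather than a re-detected boundary pixel.
* **line e** — from the midpoint of line b, perpendicular to it, toward the
  articular surface, ending at the inner surface of the subchondral plate.
  One third of its length is **s2**. Operationally the plate is found by
  walking the ray out to the innermost edge of the outermost cartilage run
  and then back inward through the contiguous bone attached to it; the run
  must be at least `plate_min_run` px (default 3). Searching outward from
  the head interior instead would latch onto the first trabecula on the
  path — trabecular struts are wider than any sensible minimum-run
  threshold — which is why the cartilage-anchored search is used.

Head height — the reference distance for the cortical measuring levels — is
the distance along line a from line c to the most proximal point of the
articular cartilage.

## Regions and measuring sites

Seven cancellous regions are cut from the section, all clipped to the
*cancellous domain*: the filled tissue envelope minus cartilage and minus the
peripheral compact bone. The compact bone is identified as the connected
bone component(s) touching the envelope boundary, which removes the cortical
lamellae, the head rim and the subchondral plate in one step without a
thickness-dependent erosion. A consequence worth knowing: a trabecula in
direct pixel contact with the cortex would be absorbed into the compact
component and excluded; the synthetic generator keeps a 2 px clearance, and
on real masks a one-pixel opening between shell and trabeculae achieves the
same.

* `h` — head cancellous bone: the articular side of line b within radius
  |line e| of the head center.
* `subchondral` / `inner` — the split of `h` at distance s2 from the plate's
  inner surface; they tile `h` exactly.
* `sc1`, `sc2` — two s2-thick subcapital bands parallel to line b on its
  distal side, sc1 adjacent to the neck. The bands span the column under the
  articular chord (|offset along line b| ≤ half the chord); without that
  bound the bands would be unbounded slabs and would overlap the metaphyseal
  strips near the caudal end of line b. With it, regions are pairwise
  interior-disjoint up to a sliver that is subtracted from the strips.
* `m1`, `m2` — medial metaphyseal strips of width s1 whose long boundaries
  are the s1 subdivisions of the medial segment of line c, m1 medial-most.
  The source construction fixes only the long boundaries; the distal extent
  is a parameter (`m_strip_len`, default 2 s1) recorded in the run
  configuration and reported with results.

Measuring sites: subchondral plate thickness along rays from the head center
every `angular_step` degrees across the articular semicircle, endpoints
included (19 rays at the default 10°; the inclusive-endpoint convention is a
package decision — the construction only fixes the interval); cortical
thickness at `n_segments + 1` levels per side spaced head height /
`n_segments` along line a starting at line c (9 levels per side at the
default 8).

## Measurement operators

**BV/TV** is pure pixel counting: 100 × bone pixels / total pixels in the
region, pixels assigned by the pixel-center rule with no partial-pixel
weighting. This matches counting-based histomorphometry and makes every
expected value exactly computable in tests.

**Plate thickness** per ray: find the outermost cartilage run along the ray,
step inward from its inner edge through the contiguous bone run (allowing a
half-pixel rasterization gap), and report the distance from the end of the
cartilage to the first marrow sample, in mm. Rays that cross no cartilage
yield a missing value, which is excluded from statistics, never zero-filled.
The outward-then-inward walk makes the measure robust to trabeculae further
along the path; a trabecula collinear with the ray and touching the plate
would still inflate the local reading — a limitation shared with any 1D
definition of plate thickness.

**Cortical thickness** per site: the periosteal contour point closest to the
level on the requested side (the level band widens automatically at the
first level, where the contour point sits just distal of the cartilage
margin), a local tangent from the outermost contour pixels of neighbouring
rows, and the contiguous bone run along the inward normal. If fewer than
three contour points support a tangent, the measurement falls back to a
horizontal chord and flags the row. Measuring along the normal, not a
horizontal chord, keeps oblique contours (e.g. the curved calcar) from
inflating thickness by 1/cos of the obliquity.

## Donor grouping and statistics

Donors are allocated by the WHO densitometric rule on the distal-radius DXA
T-score: osteoporotic at T ≤ −2.5, normal at T ≥ −1.0, osteopenia between.
Osteopenic donors are excluded from the two-group comparison with a logged
warning. Both boundary values are inclusive toward their band, the usual
reading of the WHO thresholds.

Test selection is gated per sample by Shapiro–Wilk at `alpha_gate` (default
0.05): within a donor group, if every region's sample passes, regional
values are compared by one-way repeated-measures ANOVA (donor as error
stratum) with pairwise paired-t contrasts; if any cell fails, every pairwise
contrast uses the related-samples Wilcoxon signed-rank test (exact null for
n ≤ 25 without ties or zeros, normal approximation with continuity
correction otherwise). Between groups, each variable uses a Welch t-test
when both samples pass the gate and an independent-samples Wilcoxon rank-sum
test otherwise — the source workflow names a related-samples test for the
between-group leg, which is internally inconsistent for unpaired donors, so
the independent-samples rank test is used on that path. All p-values are
Bonferroni-adjusted within their comparison family (the pairs of one
within-group family; the 7 regions, 19 plate sites or 18 cortical sites of a
between-group family), not across families; the family scope is configurable.
No sphericity correction is applied to the repeated-measures step by default.

A discreteness limit worth stating plainly: with 6 donors per group the
two-sided exact signed-rank p can never fall below 2/64, so after Bonferroni
over 3 pairs no within-group contrast can reach 0.05 on the nonparametric
path. With Gaussian-like data the gate routes the family parametrically about
86% of the time (three cells at the 5% gate level); in the remaining runs the
within-group family is honestly non-significant by construction. This is a
property of the gated workflow at n = 6, not of the implementation.

## The synthetic-section generator

Because no specimen data ship with the package, every stage is validated on
generated sections with known ground truth. The generator draws an idealized
frontal proximal humerus: a circular head (default radius 20 mm) carrying a
1.0 mm articular cartilage band and a subchondral plate (default 0.5 mm,
optionally an angular profile) over the proximal-medial semicircle (neck
tilt 45°, approximating a 135° neck–shaft angle); a metaphysis with a
calcar-like, initially vertical medial flare joining a 24 mm parallel-sided
shaft; cortical shells drawn by thresholding the envelope's Euclidean
distance transform at a per-side, per-level thickness profile (default
medial 0.8→3.0 mm, lateral 0.8→2.5 mm from line c distally); and a
trabecular interior from a seeded dead-leaves process: oriented ellipses
(strut width 0.15 ± 0.04 mm, elongation 2.5–5) placed independently per
ground-truth region until each region's pixel-counted bone fraction lands on
its target (rounded to the nearest achievable pixel count, so within half a
pixel of the target fraction; the drawn cartilage arc overshoots its nominal
endpoints by 2 px so endpoint rays still cross it). A dead-leaves process was
chosen over any remodeling-inspired model because the only property the
measurement chain consumes is the bone-area fraction, which dead leaves
controls directly and seedably.

Default targets for the normal-like template are h 25% (subchondral and
inner both 25%), sc1 18%, sc2 20%, m1 = m2 = 24.5%, surrounding cancellous
bone 20%. The osteoporotic-like template multiplies these by region-specific
factors (subchondral 0.78, inner 0.72, sc1 0.55, sc2 0.65, m1 0.60, m2 0.65,
elsewhere 0.70) — reductions strongest in the first subcapital band and the
medial metaphysis, and the medial metaphyseal targets sit just below the
head value in the normal template (a tendency, not a significant deficit).
These choices reproduce the qualitative pattern the workflow is meant to
detect: group differences in every cancellous region, head-versus-metaphysis
differences only under osteoporotic-like loss, no subchondral plate change
(plates are drawn identically in both groups), and a thinner distal medial
cortex in the osteoporotic-like group. The published source for this design
reports its regional values only graphically, so the absolute percentages
are generator conventions, not transcriptions.

Per-donor variation is Gaussian jitter (sd 0.06) on the logit of each target
fraction, which keeps targets inside (0, 1) and yields roughly ±1
percentage-point donor scatter at the default levels. T-scores are drawn
from group-specific normals truncated to the WHO band of the group label
(normal: mean 0.3, sd 0.8, ≥ −1; osteoporotic: mean −4.0, sd 1.0, ≤ −2.5);
ages follow the group means and spreads of a plausible donor pool. Cohorts
default to 6 + 6 donors.

What the generator does *not* emulate: greyscale stain variation (inputs are
already binary), anisotropic and load-aligned trabecular architecture,
connectivity loss as a distinct degradation mode, osteophytes and cysts, and
segmentation error. Passing tests therefore demonstrate that the geometric
construction, the counting and thickness operators, and the statistical
workflow are correct and well-calibrated on sections whose truth is known —
not that any particular biological effect size will be recovered from real
stained sections.

## Numerical choices

* Working resolution 0.025 mm/px (the generator default); unit tests run at
  0.1–0.12 mm/px where sub-pixel behaviour is not the point. The validation
  suite measures 50 seeded sections end-to-end at working resolution and
  requires BV/TV within ±2 pp and thickness within max(1 px, 5%) on at least
  95% of them.
* Geometric equalities are asserted at 0.5 px, directions at 1e−9 on unit
  vectors; rays are sampled at 0.25 px with nearest-pixel lookup.
* 1-based matrix indexing with the pixel (row i, col j) centered at
  continuous (x = j, y = i); x grows rightward, y downward (image
  convention). Anatomical orientation is explicit (`medial_side`) because
  frontal sections may be mounted mirrored.
* Exact CSV round-trips: results are written with shortest-round-trip
  formatting and read back with strtod-based parsing, so values survive the
  file system bit-exactly.
* Degenerate inputs error early and specifically: overlapping masks report
  the overlap count, an undetectable plate names the search path, an empty
  region names its label, and all-equal samples route the gate to the
  nonparametric path rather than erroring.

## Known limitations

The pipeline is 2D by design: a single frontal section stands in for the
bone, as in the laboratory procedure it automates. Plate thickness at the
two endpoint rays sits at the cartilage margin and is the least stable site
on degraded real-world masks. The connected-component definition of compact
bone assumes the shell is not in pixel contact with interior trabeculae. The
repeated-measures step reports unadjusted degrees of freedom (no sphericity
correction) unless configured otherwise, matching the default behaviour of
the original analysis environment.
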