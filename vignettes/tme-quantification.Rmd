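---
title: "Quantifying motility, morphology and secretion in 3D tri-cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motility, morphology and secretion in 3D tri-cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmequant)
```

## The system being quantified

`tmequant` implements the quantitative readouts of a 3D tumor-microenvironment
model: bone-marrow-derived macrophages, fibroblasts and melanoma cells seeded
together in a collagen-I gel at densities of 2400, 600 and 200 K cells/mL (a
12:3:1 ratio — 75% macrophages at seeding) and followed by time-lapse
confocal imaging and multiplex secretion assays. Four kinds of measurements
are covered, each a module with a stable surface:

* **Motility** — per-cell average migration speed and time-averaged mean
  squared displacement (MSD) from single-particle tracking exports.
* **Morphometry** — compactness, circularity and elongation of segmented,
  projected cells.
* **Proximity** — whether macrophages that start near tumor cells move
  differently from those that start far away.
* **Secretion** — preprocessing and exploratory statistics for multiplex
  cytokine plates and single-cell secretion matrices.

A seeded synthetic generator (`sim_config()` and the `simulate_*` /
`render_masks()` functions) produces data of all four kinds with known ground
truth, so every statistic in the package can be validated end to end at desk
scale.

## Motility statistics

Average speed is defined as the mean of the absolute *net* planar
displacement per 1 h interval: a cell that wanders within an interval but
returns to its starting point contributes nothing for that interval. Spots
are first binned onto the nominal interval grid by nearest timestamp
(`resample_track()`); gaps longer than one interval split a track into
segments so that displacement is never measured across a missing frame. The
interval (default 1 h) is the frame interval of the time-lapse; tracks with a
single spot have undefined speed and are flagged rather than dropped
silently.

The time-averaged MSD of a track with positions $(x_i, y_i)$, $i = 0..N$, is

$$\mathrm{MSD}(n) = \frac{1}{N-n+1} \sum_{i=0}^{N-n}
  \left[(x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2\right],$$

with overlapping windows and planar coordinates only (a 3D variant exists
behind `use_z`, off by default, because the imaging-derived z coordinate is a
single manually assigned slice per cell and carries no dynamics). The
ensemble curve (`ensemble_msd()`) averages per-track MSD values per lag over
the tracks that reach that lag, reporting the SEM and the contributing-track
count; tracks shorter than 3 spots are excluded and counted in a QC
attribute. Tracks are *not* truncated to a common length before averaging —
instead each lag is flagged `well_sampled` only while at least half the
usable tracks contribute, which is where ensemble plots should stop. The
log-log slope of the curve (`msd_loglog_slope()`) is the standard regime
diagnostic: 1 for uncorrelated (diffusive) motion, 2 for ballistic motion.

## Shape indices and their estimators

Three dimensionless indices describe a segmented cell:

$$\mathrm{compactness} = \frac{4\pi\,\mathrm{Area}}{\mathrm{Perimeter}^2},
\qquad
\mathrm{circularity} = \frac{4\pi\,\mathrm{Area}}{\mathrm{ConvexPerimeter}^2},
\qquad
\mathrm{elongation} = \frac{\mathrm{Width}_{bb}}{\mathrm{Length}_{bb}}.$$

Compactness is 1 for a circle and falls as protrusions lengthen the
boundary; circularity uses the convex perimeter and is therefore insensitive
to concavities, so circularity ≥ compactness always, with equality exactly
for convex shapes.

Digital perimeters require an estimator, and the choice is consequential.
The raw traced 8-connected boundary chain with weights $(1, \sqrt 2)$
overestimates the length of an isotropically oriented smooth boundary by
about 5.5% (the orientation average of $\cos\theta + (\sqrt2 - 1)\sin\theta$),
which would bias a disk's compactness down to ~0.90. We therefore measure
the traced chain with the calibrated Vossepoel–Smeulders step weights (0.948
straight, 1.340 diagonal), which are unbiased in the orientation average: a
rasterized disk of radius 50 px measures within 1% of $2\pi r$. The convex
perimeter is measured in the *same* digital chain metric — each convex-hull
edge of the boundary pixel centers is decomposed into straight and diagonal
unit steps and weighted identically — so the convexity relation
(convex perimeter ≤ perimeter, equality for convex rasterizations) survives
the calibration; measuring the hull with the Euclidean metric instead would
let circularity fall below compactness on rectangles, which the index
definitions forbid.

The bounding box is the *minimum-area rotated* rectangle (rotating calipers
over the convex hull), not the axis-aligned box, because cell orientation in
a gel is arbitrary and elongation should be rotation-invariant; both box
dimensions receive +1 px so that a $w \times l$ axis-aligned rectangle of
pixels measures exactly $w \times l$. Compactness values marginally above 1
are a normal discretization effect and are reported as computed, with a QC
flag above 1.05. The expected discretization error of all three indices is
about 3% at linear sizes of 30 px and above, which is the tolerance the test
suite uses for rasterized fixtures (5% for the thin-armed stars, whose
boundary orientations are few and extreme).

Segmentation of projected images (`segment_projection()`) is deliberately
plain — maximum-intensity projection, global Otsu threshold, 8-connected
components, minimum-area filter — because the package's contribution is the
measurement, not the segmentation. Connectivity is 8 so that diagonal
protrusions stay attached to the cell body. Border-touching objects are
flagged truncated rather than silently measured.

## Proximity analysis

Each macrophage is paired with its nearest tumor cell by 3D Euclidean
distance at the *start* of imaging (immediately after gelation); using the
initial position only keeps the group assignment static and matches how the
imaging experiment defines proximity. The 15 closest and 15 farthest
macrophages form the close and far groups (ties broken by cell id, so the
grouping is deterministic); intermediate cells are retained with regime
`middle` for speed-versus-distance scatters. The group comparison is a
one-tailed Welch $t$-test with alternative mean(close) > mean(far): Welch
because the two groups have no reason to share a variance, one-tailed in the
direction observed for tumor-proximal macrophages, and it reduces to the
Student test when variances happen to be equal. The degenerate all-constant
case is reported as $t = 0$, $p = 0.5$ with a flag instead of an error.

## Secretion preprocessing

Plate readings below an analyte's quantifiable standard curve arrive as
`OOR<` markers. `impute_oor()` replaces each such reading with the lowest
*uncensored* value observed for that analyte — the floor-substitution rule
used with commercial multiplex panels. Because the censoring mask is kept
and the minima are always recomputed from uncensored entries only, the
operation is idempotent. An analyte censored in every sample cannot be
imputed and is left censored with a warning. Above-range saturation is not
modeled: these panels are run in their dynamic range, and an above-range
flag in input triggers a validation warning rather than a silent clamp.

Transforms follow the usual visualization pipeline: elementwise natural log
(strictly positive entries required; zeros must be lifted explicitly with a
declared `pseudo_floor`, never silently) or per-analyte z-scores using the
sample (n−1) standard deviation. Downstream statistics are intentionally
standard and delegated to base R: Pearson sample-by-sample correlations
(`cor`), agglomerative clustering on Euclidean distance with average linkage
(`hclust`; the linkage is configurable since heatmap conventions vary, and
leaf order is the deterministic lower-index-first order), and PCA on centered
data (`prcomp`). A zero-variance sample has no defined correlation and is
reported as missing with a flag, not dropped.

Single cells are classified as active secretors when at least one analyte
exceeds its positivity threshold; polyfunctionality is the count of analytes
above threshold, and ≥ 2 is reported as the polyfunctional fraction — a
convention, since the term has no universal quantitative definition.
Device-specific thresholds are rarely published, so the default
(`background_thresholds()`) is mean + 2 sd of a declared background
population, per analyte.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions of the tri-culture it
imitates: 320 cells at the 2400/600/200 K/mL composition in a
1000 × 1000 × 300 µm domain, a 100 µm tumor-proximity radius, 1 h frames,
and a 40% single-cell secretor fraction. Macrophage motion is a planar
persistent random walk: headings evolve by wrapped-normal turning angles
whose mean resultant length is the `persistence` parameter (0.6 by default,
giving the short-lag superdiffusive, long-lag diffusive MSD typical of
migrating macrophages), and step lengths are `speed × dt` with a 20%
coefficient of variation. Motion is planar with a fixed z because the
measured statistics (speed, MSD) are planar; a 3D walk would decouple the
configured regime speed from its planar ground truth. Proximity modulates
the *mean* speed (12 µm/h within 100 µm of a tumor cell at seeding versus
6 µm/h beyond — illustrative values on the observed scale, since no
calibrated speeds are available), fibroblasts and tumor cells get only a
0.3 µm/step jitter, and boundaries reflect, which preserves speed statistics
where absorption or clipping would not.

Morphology fixtures are filled polygons — disks, ellipses and $k$-armed
stars — rasterized by pixel-center membership, with analytic area,
perimeter, hull perimeter and rotated-bounding-box truth computed from the
continuous polygon (closed forms for disks). Secretion plates are log-normal
per analyte with a planted fold-change on a subset of analytes and
below-LOD censoring; single-cell matrices plant secretors (with a
guaranteed-detectable first analyte, so classification against ground truth
is exact) in block-profile clusters over background noise held strictly
below threshold.

None of this emulates real imaging noise: no segmentation errors, no track
fragmentation or identity switches, no cell division, death, or
density-dependent crowding, no cytokine diffusion or temporal evolution of
secretion, and no spatial correlation between morphology and position.
Passing tests therefore certify the *statistics* — that speeds, MSD curves,
indices, group tests and plate transforms compute what they claim on data
with known truth — not the robustness of upstream detection or segmentation
on real microscopy.

## Numerical and design choices worth knowing

* All generator randomness flows from one integer seed per config
  (sub-streams are derived with fixed offsets per output type), and
  `run_pipeline()` reruns are byte-identical.
* Allocation of cell counts from densities uses largest-remainder rounding,
  so counts always sum to the requested total.
* Nearest-tumor ties are broken by lowest tumor id; distance ties in the
  close/far ranking by macrophage id.
* `msd()` refuses non-uniform time spacing rather than silently
  interpolating; resampling is an explicit upstream step.
* The boundary centroid versus area centroid distinction for "cell center"
  matters for irregular shapes; tracking exports already supply the center
  used to build tracks, so the package takes coordinates as given.
* Test and fixture sizes (hundreds of tracks, 20-sample plates, 1000-cell
  matrices, ≤ 900 px images) are chosen so the full suite runs in seconds
  while keeping Monte-Carlo tolerances (10% on speed recovery, ±0.04 on a
  0.4 secretor fraction, ±0.02 on test size at the 0.05 level) derivable
  from sampling error.

## Known limitations

The perimeter calibration is exact only in the orientation average; a single
straight edge at 22.5° can still be ~3% off, which is why thin-armed star
tolerances are wider. Welch's test is the only implemented group comparison
(no non-parametric alternative). The clustering module exposes linkage but
not distance; Euclidean on z-scores is the only supported metric. The
pipeline treats each input table as one experiment — pooling across
replicate gels, and any correction for testing several proximity contrasts,
is left to the caller.
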