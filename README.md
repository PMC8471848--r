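# tmequant

Quantification toolkit for 3D tumor-microenvironment tri-cultures:
macrophages, fibroblasts and melanoma cells embedded together in collagen-I
gels, followed by time-lapse confocal imaging and multiplex secretion
assays. The package is for researchers who have tracking exports, projected
label images, or cytokine plates from such co-cultures and need the
downstream numbers: how fast cells move, how protrusive they are, whether
tumor-proximal macrophages behave differently, and what the secretion
profiles look like after proper preprocessing.

## What it computes

**Motility.** Per-track average speed — the mean absolute *net* planar
displacement per 1 h interval — and the time-averaged mean squared
displacement

```
MSD(n) = 1/(N−n+1) · Σ_{i=0..N−n} [(x_{i+n}−x_i)² + (y_{i+n}−y_i)²]
```

with overlapping windows, plus ensemble mean ± SEM curves and the log-log
slope (1 = diffusive, 2 = ballistic).

**Morphometry.** For each labeled cell: compactness `4π·Area/Perimeter²`,
circularity `4π·Area/ConvexPerimeter²`, and elongation
`Width_bb/Length_bb` from the minimum-area rotated bounding box, with
two-bin classification at compactness 0.8. Perimeters use the traced
8-connected boundary with calibrated (Vossepoel–Smeulders) step weights, so
a digital disk measures within 1% of 2πr.

**Proximity.** Each macrophage is paired with its nearest tumor cell (3D
distance at the start of imaging); the 15 closest versus 15 farthest are
compared with a one-tailed Welch t-test on average speed.

**Secretion.** Multiplex plate preprocessing (`OOR<` below-range markers →
analyte-minimum imputation → ln or z-score transforms), Pearson sample
correlations, hierarchical clustering, PCA, and single-cell secretor /
polyfunctionality classification.

**Synthetic ground truth.** A seeded generator produces all four data kinds
— persistent-random-walk trajectories whose speed depends on initial tumor
distance, parametric shape panels (disks, spindles, stars) with analytic
index truth, and censored log-normal plates with planted group structure —
so every statistic is testable against known answers.

## Worked example

The numbered scripts under `analysis/` run the full workflow on synthetic
data and write their tables under `results/`. Stage 1 seeds the 12:3:1
tri-culture and simulates imaging and a secretion plate; stages 2–5 consume
those files:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_motility.R
Rscript analysis/03_proximity.R
```

which prints

```
Seeded 320 cells:
fibroblast macrophage      tumor
      18.8       75.0        6.2
Macrophages within 100 um of a tumor cell: 55 of 240 (23%)

Average speed (um/h) by tumor-proximity regime:
  regime mean_speed sd_speed n_tracks
1  close     11.992   0.7603       55
2    far      5.981   0.3728      185
3 static      0.383   0.0591       80

close group mean speed: 11.94 um/h
far group mean speed:   5.94 um/h
one-tailed Welch t = 27.30, p = 8.02e-17
```

Reading: 75% of seeded cells are macrophages (the 12:3:1 composition); 55 of
240 macrophages start within the 100 µm proximity radius of a tumor cell.
Their recovered mean speeds (12.0 and 6.0 µm/h) match the configured
close/far regimes, and the top-15-closest versus top-15-farthest Welch
comparison detects the difference decisively. Stages 4 and 5 do the same
for shape indices (measured vs analytic error ~1–3%) and plate
preprocessing.

The same stages are available programmatically:

```r
library(tmequant)
cfg <- sim_config(seed = 1)
pop <- simulate_population(cfg)
traj <- simulate_trajectories(pop, cfg)
pa <- proximity_analysis(traj$tracks, pop, k = 15)
pa$test$p
#> [1] 8.018572e-17
```

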