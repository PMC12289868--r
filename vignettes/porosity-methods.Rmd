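---
title: "Quantifying intra-colonial porosity microenvironments from micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-colonial porosity microenvironments from micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralpore)
```

## The problem

Endolithic microorganisms — dominated in many corals by the boring alga
*Ostreobium* — form a pigmented "green band" a few millimeters beneath the
living tissue of massive coral skeletons. Their boring activity excavates
channels typically narrower than 10 µm, well below the resolution of a
laboratory micro-CT scan (~24 µm voxels). Such sub-resolution porosity is
still detectable: a voxel partially occupied by micro-channels attenuates
X-rays at a level intermediate between solid aragonite and air (the partial
volume effect). This package quantifies that signal and asks where, along
the vertical (apical–basal) axis of a fragment, microporosity and
macroporosity change, and whether those changes align with the green band
measured independently on the cut face with a stereoscope.

Four response variables are computed per sampling window, all as
percentages of the *colony* volume in the window (mask voxels excluded):

* **MiP** — microporosity, the volume fraction of intermediate-intensity
  voxels;
* **MaP** — macroporosity, the fraction of air-intensity voxels enclosed in
  the colony;
* **TP** — total porosity, defined as `MiP + MaP`;
* **SVF** — solid volume fraction.

Per window `MiP + MaP + SVF = 100` by construction. Fragment-level means
average windows with unequal colony volumes, so mean TP and mean SVF need
not sum to 100 across fragments and are deliberately not renormalized.

## Pipeline

### Masking

A voxel is air when its intensity falls below an air threshold; by default
that threshold is the *lower cut of a three-class Otsu criterion* applied
to the whole volume. A two-class Otsu is tempting but unreliable here: on
the trimodal air/micropore/solid histogram its single cut can settle just
below the micropore level, and with noise the boundary flood then leaks
through surface micropore voxels, swallowing the entire internal pore
network (whose air phase typically percolates).

The mask then combines two conventions:

1. **Exterior-connected air is not a pore.** Air voxels reachable from the
   volume boundary by a 6-connectivity flood are mask; enclosed voids stay
   colony voxels (candidate macropores). Voids that a channel connects to
   the exterior are, per the same rule, masked. 6-connectivity is the
   default because it cannot leak diagonally through one-voxel walls;
   26-connectivity is available.
2. **Non-colony structures are mask.** The colony is the non-air region
   flooded from the voxel nearest the centroid of all non-air voxels;
   every other non-air structure — the sample tube, fragment separators,
   loose shards — is mask. An intensity-plus-distance-to-face rule was
   tried first and rejected: a cylindrical tube wall is nowhere near the
   rectangular volume's faces along most of its circumference, and
   polypropylene attenuates between air and aragonite, so neither geometry
   nor intensity alone isolates it. The component rule assumes the colony
   does not touch the container; for scans where it does, a fixed
   `air_threshold` and `container_policy = "none"` are available.

### Segmentation

Non-mask voxels are split by two thresholds `t_low < t_high` into air
(`< t_low`), micropore (`[t_low, t_high)`) and solid (`>= t_high`). The
default selects both cuts by a three-class Otsu criterion over the
histogram of colony voxels only (256 bins); fixed thresholds are a config
option. Micropores are counted as whole voxels — no partial-volume
weighting — matching the categorical four-phase voxel model. No
morphological cleanup is applied by default.

### Porosity mapping

Windows are non-overlapping cubes of 0.9 mm (rounded to a whole voxel
count: 37 voxels at 24.3 µm, i.e. an effective 0.8991 mm), anchored at the
bounding box of the colony mask. Edge windows clipped by the box are kept
if at least `min_colony_fraction` (default 0.05) of their voxels are
colony; emptier windows are flagged invalid and excluded from statistics.

### Vertical profiles and normalization

The vertical profile averages each variable over the valid windows of
every Z level. Two normalizations make fragments comparable:

* **Coordinates.** `z_norm = (z - min(z)) / (ref_max - ref_min)`, the
  denominator taken from the largest selected fragment, then
  `z_mm = z_norm * conversion + correction` with defaults 8 mm (the
  largest porosity map's vertical length) and 0.45 mm (half a sampling
  interval, since a profile point represents the middle of its window).
  The largest fragment therefore spans 0.45–8.45 mm. When recovered peak
  locations must be compared with physically measured ones,
  `mm_scale_from_reference()` returns the conversion/correction pair that
  maps window indices exactly onto physical window centers.
* **Variables.** `v_norm = (v - min(v)) / (max(v) - min(v))` within each
  fragment. Pooling raw values across fragments with different baseline
  porosities flattens the intra-colonial gradient; the range-normalized
  values preserve it. Constant profiles raise an explicit zero-range
  error rather than dividing silently.

### LOESS and extremum localization

Profiles are smoothed with local quadratic regression (tricube weights,
`surface = "direct"` for determinism), default span 0.3, evaluated on a
200-point grid over the data range (no extrapolation). Extrema are read
off the smoothed curve, not the raw points. Two numerical choices matter
on short profiles:

* A span of 0.3 over the ~8 levels of a desk-scale fragment would leave
  fewer points in a neighborhood than a quadratic can identify, so
  `find_band_extrema()` floors the span at `3.2 / K` for `K` profile
  levels. The floor is inactive once profiles carry ≥ 11 levels.
* Extrema found at the first or last grid point are flagged
  `at_boundary`; the band localization prefers the strongest *interior*
  turning point and falls back to the global extremum only when the curve
  is monotone. Fragment ends systematically under-sample macropores (a
  void cut by the fragment face is exterior-connected and masked), which
  otherwise draws valleys to the boundary.

Ties between equal grid values break towards the apical end.

### Zones and statistics

The stereoscope-measured band interval `[low, high]` partitions the
profile into coral tissue (`z < low`), green band (`low <= z <= high`) and
skeleton (`z > high`). The statistical layer mirrors the standard design:
Spearman correlations between variables along Z; one-way ANOVA plus Tukey
HSD across the three zones of range-normalized values (normality and
homoscedasticity checks are *reported* — Shapiro–Wilk on residuals,
Levene — but never silently switch the test); Spearman concordance between
extremum locations and band midpoints plus a two-group ANOVA on the paired
location sets; species comparisons by ANOVA/Tukey and the unbalanced
location comparison by Kruskal–Wallis; Pearson correlations of fragment
means. Tukey adjustment is applied within each family (one variable, one
grouping) with no global correction across variables. Profile points along
Z are serially correlated; the zone ANOVA treats them as independent,
matching the published design, and this caveat is deliberate.

## The phantom generator

`generate_phantom()` builds fragments with exact ground truth so every
stage is testable without scan data: a solid cylinder (inside an air
margin and optional tube wall) carrying

* **macropores** — overlapping spheres from an inhomogeneous Boolean
  model. The z-intensity is calibrated as
  `lambda(z) = -log(1 - f(z)) / E[v]` so the expected void fraction tracks
  the target macroporosity profile exactly under overlap. Default radii
  0.05–0.2 mm: resolvable at 24.3 µm but small against the ~2.4 mm phantom
  colony (real fragments are ~10 mm across; commensurately large spheres
  would make each window a count of one or two voids and the windowed
  percentages unusable). Spheres are kept ≥ 1.5 voxels inside the colony
  surface: at the default 35% void fraction the macropore network
  percolates, and an unsealed network touches the surface and would be
  masked wholesale as exterior-connected — whereas real fragments retain
  measured macroporosities up to ~47%, implying mostly enclosed voids at
  scan resolution.
* **micropores** — single voxels of intermediate intensity (the
  partial-volume proxy; true channels are sub-resolution by definition),
  drawn per voxel at a z-dependent rate.
* **a band** — a Gaussian bump in micropore rate with a matching dip in
  macropore rate, centered 2.5 mm below the apex by default, width 1.2 mm
  (the mean of the measured green-band widths across the twelve profiled
  fragments), with an optional skew parameter for the apical asymmetry
  seen in real profiles (default symmetric). Defaults put fragment
  means inside the observed ranges (MiP ≈ 4–11%, MaP ≈ 20–47%) without
  being fitted to them.
* **noise** — additive Gaussian, default σ = 5% of the solid–air gap.

Truth labels apply the same masking conventions as the pipeline
(exterior-connected air, disconnected shards and the container are mask),
so that in the noiseless limit segmentation reproduces the truth voxel for
voxel — a property the tests assert exactly.

What the phantom does **not** emulate: corallite architecture and
branching filament networks, beam hardening and reconstruction artifacts,
spatially correlated noise, anisotropic pore shapes, and the gradual
secondary-aragonite infilling below the band. Passing recovery tests
therefore demonstrate that the *pipeline* is correct and well calibrated
on geometry it understands, not that real scans are free of those
additional effects.

## Validation studies and chosen problem sizes

`band_recovery_study()` runs the full pipeline on a cohort of phantoms
(default 20) with band centers drawn uniformly from 1.5–4.5 mm, at
120 × 120 × 300 voxels (a 2.4 × 2.4 × 7.1 mm colony, ~8 profile levels) —
large enough for ~9 windows per level and stable windowed percentages,
small enough that a cohort runs in about a minute. On these defaults the
microporosity peak lands within one window (±0.9 mm) of the true center
in essentially every fragment (mean absolute error ~0.2 mm), the
macroporosity valley — a shallower, noisier feature riding on the Boolean
sphere fluctuations — within ±1.8 mm in roughly 75–85% of fragments
depending on the cohort draw, the cohort-level Spearman between peak
locations and band centers exceeds 0.95, and the per-fragment MiP–MaP
profile correlation is negative in every run observed — the synthetic
analogues of the reported field concordances. `calibrate_zone_anova()` checks the zone ANOVA by
simulation: the type-I error at α = 0.05 stays within [0.03, 0.07]
(1000 replicates, n = 30/zone) and power for a five-standard-deviation
band shift is ~1.

## Known limitations

* The component-based container mask assumes an air gap between colony and
  container; contact merges them (use a fixed threshold or adjust the
  policy).
* Micropore detection inherits every limitation of single-energy
  intensity thresholding; beam hardening or ring artifacts in real scans
  can masquerade as intermediate intensities.
* Voxel size is treated strictly as data (instrument reports may disagree
  between scan metadata and published roundings); nothing defaults it
  silently.
* The zone ANOVA ignores serial dependence along Z by design, to match the
  published analysis; its p-values are anti-conservative to that extent.
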