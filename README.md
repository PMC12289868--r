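# coralpore

Micro-CT porosity mapping of coral skeletons and the endolithic green
band.

Massive corals such as *Porites* host a community of boring microorganisms
that forms a pigmented **green band** a few millimeters beneath the living
tissue. The channels these endoliths excavate are mostly narrower than
10 µm — below the resolution of a laboratory micro-CT scan — but they
shift voxel attenuation towards values intermediate between solid
aragonite and air (the partial volume effect), which makes the
sub-resolution porosity quantifiable. `coralpore` implements the full
analysis chain for asking *where* porosity changes along the vertical
(apical–basal) axis of a skeletal fragment and whether those changes align
with the green band:

1. **Masking** — exterior air (boundary-connected, 6-connectivity flood)
   and non-colony structures (sample tube, separators) are excluded;
   enclosed voids stay in the colony as candidate macropores.
2. **Four-phase segmentation** — two thresholds, chosen by a three-class
   Otsu criterion over colony voxels (or fixed by config), label every
   voxel solid / micropore / air / mask.
3. **Porosity mapping** — the volume is tiled into 0.9 mm cubic windows;
   each window reports microporosity (MiP), macroporosity (MaP), total
   porosity (TP = MiP + MaP) and solid volume fraction (SVF), all as
   percentages of the window's colony volume (MiP + MaP + SVF = 100 per
   window).
4. **Vertical profiles** — per-level means ± s.e.m., normalized across
   fragments with
   `z_mm = z_norm * 8 mm + 0.45 mm`, `z_norm = (z - z_min) / (Z_max - Z_min)`
   (denominator from the largest fragment) for coordinates and
   `v_norm = (v - v_min) / (v_max - v_min)` within fragment for variables.
5. **LOESS extrema** — local quadratic smoothing localizes the
   microporosity peak and macroporosity valley; their concordance with the
   stereoscope-measured band is tested by Spearman correlation and a
   two-group ANOVA.
6. **Zone / group statistics** — ANOVA + Tukey HSD across the coral
   tissue / green band / skeleton zones and across species,
   Kruskal–Wallis for the unbalanced location contrast, Pearson
   correlations of fragment means.

A synthetic phantom generator with exact voxel ground truth
(`generate_phantom()`) drives validation of every stage, so the package is
fully testable without scan data. Scan volumes are read from NetCDF
(`read_tomogram()`), fragment metadata (species, location, depth,
green-band interval) from YAML (`load_fragment_metadata()`; a file for the
twelve profiled *Porites* fragments ships in `inst/extdata/`).

## Worked example

Simulate a fragment with a band centered 2.5 mm below the apex, run the
pipeline, and recover the band from the porosity signal alone:

```r
library(coralpore)

ph  <- generate_phantom(synthetic_truth(seed = 42))
seg <- segment_tomogram(ph$tomogram)
pm  <- compute_porosity_map(seg)
vp  <- extract_vertical_profile(pm)

fragment_mean(pm)
#>   variable      mean       sem  n
#> 1      mip  6.376581 0.2203513 72
#> 2      map 29.128760 1.4225425 72
#> 3       tp 35.505341 1.2744690 72
#> 4      svf 64.494659 1.2744690 72

find_band_extrema(vp)
#>   variable   kind location_mm     value at_boundary
#> 1      mip   peak    2.315521  8.877656       FALSE
#> 2      map valley    2.695041 12.005161       FALSE

correlate_profiles(vp$mip_mean, vp$map_mean)
#> spearman correlation: rho = -0.786, p = 0.0208, n = 8
```

The microporosity peak (2.32 mm) and macroporosity valley (2.70 mm) both
land within one sampling window (0.9 mm) of the true band center at
2.5 mm, and micro- and macroporosity are inversely correlated along the
profile — the intra-colonial signature of the endolithic band. Fragment
means (MiP ≈ 6%, MaP ≈ 29%) sit inside the ranges observed in real
*Porites* fragments.

A cohort-level validation (20 phantoms, random band centers) with recovery
rates and peak-vs-band concordance is one call:
`print(band_recovery_study(n_fragments = 20, seed = 1))`.

The stages are also scriptable end to end with
`run_pipeline(run_config(seed = 7), out_dir = "out")`, which writes the
phantom, labelled volume, porosity map, profiles, extrema and statistics
plus a checksummed manifest, or from a shell via the thin wrapper
`inst/scripts/coralpore.R`.

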