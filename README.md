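# spectiq

Simulation and analysis of how acquisition time and reconstruction
parameters drive SPECT image quality, measured on a digital NEMA IEC body
phantom.

Whole-body SPECT/CT is limited by scan time: shorter acquisitions mean
fewer counts, more noise, and poorer detectability of small lesions. The
experimental design this package reproduces answers "how short can the
acquisition be?" with a single gated phantom scan: an artificial trigger
splits every projection view into 15 one-second Poisson bins, partial bin
sums (1–3, 1–8, 1–15) emulate 3, 8 and 15 s/view acquisitions from one
noise realisation, and every combination of OSEM iterations and Gaussian
post-filter width is reconstructed and scored. `spectiq` implements the
whole chain in software:

* **Digital phantom** — six fillable spheres (37, 28, 22, 17, 13, 10 mm
  internal diameter) at an 8.5:1 sphere-to-background concentration
  ratio, from the literal bench arithmetic (214.2 MBq in 1200 ml stock,
  ~48 ml withdrawn for spheres, remainder diluted in 9787 ml background
  → 178.5 / 21 kBq/ml), digitised with sub-voxel supersampling plus a
  matching water attenuation map.
* **Acquisition simulator** — dual-head step-and-shoot geometry (60
  views/head, 120 projections, 360°, 4.8 mm pixels, circular 250 mm
  orbit), rotation-based projector with distance-dependent collimator
  blur (FWHM = 4 mm + 0.05·distance), Beer–Lambert attenuation, and
  seed-stable gated Poisson bins.
* **Reconstruction** — matched-model 3D OSEM with resolution recovery
  and attenuation correction, exact adjoint projector pair, and an
  edge-renormalised 3D Gaussian post-filter.
* **NEMA NU 2-2018 style metrics** — per-sphere contrast recovery,
  background variability over 60 background ROIs (12 deterministic
  positions × 5 slices), CNR with the Rose visibility criterion, and a
  contrast-convergence rule on the iteration grid.

The core quantities, per sphere *s*:

```
RC_s  = 100 · (C_H,s / C_B,s − 1) / (R − 1)          contrast recovery (%)
BV_s  = 100 · SD_s / C_B,s                           background variability (%)
SD_s  = sqrt( Σ_k (C_B,s,k − C_B,s)² / (K − 1) )     K = 60 background ROIs
CNR_s = (C_H,s − C_B,s) / SD_ROI                     visible iff CNR_s > 5
```

with `C_H,s` the sphere-ROI mean, `C_B,s` the mean of the matching-
diameter background ROI means, and `R` the true concentration ratio.

## Worked example

One gated realisation, 15 s/view, reconstructed at the study's operating
point (12 iterations × 8 subsets, 8 mm post-filter) on a 64³ grid:

```r
library(spectiq)

spec <- phantom_spec()
spec$fill_plan
#> NEMA IEC phantom fill plan
#>   stock: 214.2 MBq in 1200 ml -> 178.5 kBq/ml (spheres)
#>   withdrawal for spheres: 47.8 ml
#>   background: 21.0 kBq/ml in 9787 ml
#>   sphere-to-background ratio R = 8.494

vox    <- voxelize_phantom(spec, 4.8, c(64, 64, 64), supersampling = 4)
geom   <- acq_geometry(matrix_dim = c(64, 64))
nf     <- calibrate_sensitivity(forward_project(vox, geom), 1e6)
stack  <- simulate_gated_acquisition(nf, n_gate_bins = 15, seed = 7)
s15    <- sum_bins(stack, c(1, 15))           # bins 1-15 -> 15 s/view
vol    <- osem(s15, vox$mu_map, recon_params(12, 8, 0))
vol    <- gaussian_postfilter_3d(vol, 8)
layout <- build_roi_layout(spec, c(64, 64, 64), 4.8)
m      <- evaluate_volume(vol, layout, spec$fill_plan$ratio_R)
round(m[, c("sphere_mm", "RC", "BV", "CNR")], 1)
#>   sphere_mm   RC   BV  CNR
#> 1        37 93.8  9.9 71.3
#> 2        28 73.8 12.5 44.1
#> 3        22 62.9 16.3 29.0
#> 4        17 32.3 17.6 13.7
#> 5        13 20.4 21.0  7.3
#> 6        10  9.3 23.4  3.0
```

Reading the table: recovery falls with sphere diameter (partial-volume
effect), noise (BV) is higher for the smaller background ROIs, and at
this count calibration (10⁶ expected counts for the full 15 s scan) the
13 mm sphere clears the Rose criterion (CNR > 5) while the 10 mm sphere
does not. Summing fewer bins (`sum_bins(stack, c(1, 3))`) shows noise
rising as the effective acquisition shortens.

The numbered scripts under `analysis/` run the full study — phantom
construction (`01`), gated acquisition and the 3/8/15 s resampling table
(`02`), the complete iteration × filter × duration sweep over three
realisations (`03`), and convergence detection plus the trade-off
figures (`04`) — writing tables and figures under `results/`.

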