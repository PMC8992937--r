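---
title: "Acquisition time and OSEM parameters for SPECT image quality: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acquisition time and OSEM parameters for SPECT image quality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spectiq` reproduces, end to end and in software, the classic
gated-phantom experiment used to decide how short a SPECT acquisition can
be made before image quality degrades: a NEMA IEC body phantom is imaged
once at the full protocol duration with an artificial gating trigger, the
gate bins are re-summed into shorter effective acquisitions, every
combination of OSEM iterations and Gaussian post-filter is reconstructed,
and per-sphere contrast recovery (RC), background variability (BV) and
contrast-to-noise ratio (CNR) decide the operating point. This vignette
documents the models, the defaults and their rationale, the numerical
choices, and what the synthetic study can and cannot say about a physical
scanner.

## The digital phantom

The phantom is the standard six-sphere IEC body phantom: fillable spheres
of internal diameter 37, 28, 22, 17, 13 and 10 mm on a 57.2 mm-radius
ring in one transaxial plane, inside a torso-shaped cavity. Two pieces of
geometry are not standardised anywhere we could rely on and are package
choices:

* **Body outline.** We model the torso cross-section as a 300 x 230 mm
  ellipse extruded over 180 mm. The resulting cavity volume (~9750 ml)
  matches the 9787 ml background compartment of the physical phantom to
  0.4%, which a rounded-rectangle outline does not; the semi-axes and
  length are configurable.
* **Sphere angular placement.** Spheres sit at 60-degree spacing with the
  largest sphere on the +x major axis, which leaves the most background
  clearance around the large spheres for ROI placement.

The fill plan reproduces the bench arithmetic literally: a stock of
`total_activity` MBq in `stock_volume` ml sets the sphere concentration;
the sum of the six sphere volumes (`(pi/6) d^3`, about 48 ml) is
withdrawn; the remainder is diluted into the 9787 ml background. With the
default 214.2 MBq / 1200 ml preparation this gives 178.5 and 21 kBq/ml
and a concentration ratio R = 8.5, and the ratio is by construction
independent of the total activity. We read the printed 9787 ml as the
*final* background volume; that is the only reading consistent with the
printed 21 kBq/ml.

Digitisation assigns each voxel the sub-voxel volume-fraction-weighted
concentration on a `supersampling`^3 lattice (default 4). At the native
4.8 mm voxel size this bounds the total-activity digitisation error well
below 1%; sphere-volume errors shrink roughly linearly in the
supersampling factor. The attenuation map is water (0.154 cm^-1 at
140 keV) inside the outline and air outside; sphere walls, filler caps
and the optional lung insert (off by default, since the study
configuration does not use it) are not modelled.

## The projection simulator

A rotation-based projector stands in for the camera. For each of the 120
views (60 per head, two heads, 360 degrees, step-and-shoot) the activity
and attenuation volumes are rotated into the detector frame by bilinear
interpolation, every constant-distance plane is blurred with the
distance-dependent collimator response, attenuated by the Beer-Lambert
transmission integral (half-voxel self term) to the detector, and summed
along the rays.

* **Orbit.** Circular at 250 mm radius. The physical protocol uses a
  body-contoured orbit, but no contour data exists to reproduce; the
  radius is configurable.
* **Collimator model.** Gaussian FWHM = 4 mm + 0.05 mm/mm of distance, a
  generic low-energy high-resolution parameterisation chosen so the
  reconstructed-image resolution at the orbit radius lands in the
  10-12 mm range typical of such protocols.
* **Blur implementation.** Per-plane blurring uses an incremental
  Gaussian cascade: marching plane by plane towards the detector, the
  accumulated projection is convolved with a small kernel whose discrete
  variance equals the variance increment between neighbouring planes.
  Because variances add under convolution, each plane receives exactly
  its distance-dependent blur variance with a point-spread function that
  is Gaussian to central-limit accuracy; a point source projected at two
  depths reproduces the intended FWHM to well under half a pixel.
* **Sensitivity.** The physical count level is not reproducible from the
  published protocol, so the simulator is calibrated to a target total:
  by default the full 15 s acquisition totals 1e6 expected counts over
  all 120 projections. All count-level-dependent results (BV, CNR) are
  therefore comparable only in trend, not in absolute value, with a
  physical acquisition.
* **Scatter is not simulated**, and consequently the reconstruction
  needs and has no scatter correction. This is the one deliberate
  departure from the physical processing chain, which used a Monte Carlo
  scatter estimate.

Gating draws each of the 15 one-second bins as an independent Poisson
realisation of `rate x 1 s`. Each bin uses its own deterministic RNG
substream derived from the user seed, so simulating more or fewer bins
never perturbs the draws of other bins, and summing bins 1-3 / 1-8 /
1-15 reproduces the 3 / 8 / 15 s datasets as nested subsets of one
realisation — exactly the design of the physical experiment, where the
durations differ only by which gate bins are summed.

## Reconstruction

`osem()` implements the classic multiplicative ordered-subset EM update
`x <- x * backproject_S(y_S / forward_S(x)) / backproject_S(1)` with the
*same* projector used for simulation (matched-model reconstruction):
resolution recovery includes the distance-dependent blur in both forward
and backprojection, and attenuation correction uses the true simulated
mu-map (perfect registration). The rotation operator's adjoint is the
exact scatter transpose of the interpolation gather, so forward and
backprojection form an exact adjoint pair; this makes the EM monotone
likelihood property and count conservation hold to floating-point
accuracy on matched models, and both are asserted in the test suite.

Numerical choices, all places where vendor implementations are silent or
proprietary:

* Views are assigned to the 8 subsets by stride (view i to subset i mod
  8), maximising angular spread per subset; subsets are visited in index
  order. "Iterations" counts full passes over all subsets, so the 4-24
  study grid corresponds to 32-192 updates.
* The initial estimate is uniform 1.0 inside a cylindrical support mask.
* Zero-guard: measurement ratios where the forward projection is below
  1e-12 of its mean are set to 0 (not 1), and voxels with zero subset
  sensitivity stay 0; non-negativity is preserved at every subiteration.
* The post-reconstruction 3D Gaussian filter (sigma = FWHM / 2.355,
  isotropic) renormalises its truncated kernel at grid edges, so
  interior sums are preserved and no flux is invented at the boundary;
  FWHM 0 returns the volume bit-identically.
* The parameter sweep warm-starts: one OSEM run per duration records
  snapshots at each grid iteration count, valid because OSEM iterations
  compose; `warm_start = FALSE` reconstructs each cell independently and
  is tested to agree.

## Image-quality analysis

ROI placement follows the NU 2-2018 pattern: a circular ROI matching
each sphere's internal diameter on the central slice through the sphere
centres; 12 background positions for 37 mm ROIs found by a deterministic
(seed-free) greedy search over a 2 mm candidate lattice, tried
boundary-first, under the standard rules — ROI edge at least 15 mm from
the phantom margin and from every sphere surface, ROIs non-overlapping;
smaller ROIs concentric within the 37 mm ones; the pattern replicated on
the central slice and two slices each side (+-4.8 and +-9.6 mm; the
standard's +-1 and +-2 cm rounded to the 4.8 mm slice pitch), giving 60
background ROIs per diameter. A pixel belongs to a circular ROI when its
centre lies inside the circle; a supersampled fractional-area weighting
is available as an option. With the centre rule, the digitised ground
truth itself scores slightly below 100% recovery for supersampled
phantoms (partial-volume pixels at the sphere rim are averaged into the
ROI); the binary-digitised phantom scores exactly 100% and is the
reference for convergence tests.

The metrics are, per sphere `s` with background ROI means `C_B,s,k`:

* `RC_s = 100 (C_H,s / C_B,s - 1) / (R - 1)` — contrast recovery;
* `BV_s = 100 SD_s / C_B,s`, with `SD_s` the sample standard deviation
  (K - 1 = 59 denominator) over the K = 60 background ROI means;
* `CNR_s = (C_H,s - C_B,s) / SD_ROI`, visible under the Rose criterion
  iff `CNR_s > 5` (strictly).

`SD_ROI` is ambiguous in the source formulation; the package default
takes it equal to `SD_s` — the only standard deviation the NEMA-style
analysis defines — and records the choice in the output (`sd_roi_mode`);
a within-ROI pixel SD averaged over background ROIs is available as the
alternative. Background means and SDs pool all 60 ROIs across the five
slices. All three metrics are invariant under positive rescaling of the
volume, so reconstructions in arbitrary units are analysed directly.

Contrast-recovery convergence on an iteration grid is declared at the
smallest grid iteration from which every subsequent relative change
`|RC(i+1) - RC(i)| / RC(i)` stays below the threshold (default 3.5%,
configurable — the source text quotes both eight iterations for onset
and twelve for stability, so no single canonical value is assumed).

## Study sizes, runtime and limitations

The shipped analyses and tests run the full 120-view geometry on a 64^3
grid at the native 4.8 mm voxel size (the 300 x 230 x 180 mm phantom
fits with margin), where one 12-iteration matched-model reconstruction
takes roughly 10 s on one core. The trend-replication suite uses ten
gated realisations, durations 3/8/15 s, reconstructions to 12 iterations
(snapshots at 4 and 12) and post-filters 0/8 mm; the analysis scripts
run the full 4-24 iteration and 0/4/8/12 mm filter grid on three
realisations. A 128^3 grid reconstructs identically, only slower.

What passing the suite shows: the fill arithmetic is exact; the
projector obeys Beer-Lambert and the collimator FWHM model; OSEM matches
hand-computed and brute-force MLEM oracles and the EM monotonicity /
count-conservation properties; the gated-bin scheme is distributionally
identical to a single acquisition of the summed duration; and the
seed-averaged study reproduces the qualitative findings — RC rises with
sphere diameter and iteration count, BV rises with iterations and falls
with duration and filter width, removing the post-filter helps the
smallest sphere most, and small spheres need longer acquisitions to
clear the Rose criterion.

What it does not show: absolute RC/BV/CNR levels of any physical
scanner. The simulation is scatter-free, perfectly attenuation-matched
and noise-calibrated to an arbitrary 1e6-count level, so its matched
reconstruction recovers contrast more completely and with different
noise magnitudes than a vendor chain on real data; per-sphere RC at the
3 s duration is noise-dominated at this count level (which is why the
monotonicity-in-diameter check is asserted on seed-averaged RC pooled
across durations at the 12-iteration / 8 mm operating point). Septal
penetration, detector energy response, dead time and patient-contoured
orbits are out of scope.
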