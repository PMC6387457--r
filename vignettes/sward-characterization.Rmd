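---
title: "On-ground 3D sward characterization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{On-ground 3D sward characterization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swardscan)
```

## The problem

Pasture management decisions (cutting time, fertilization, reseeding) lean on
estimates of standing herbage: sward height, cover and volume as proxies for
dry biomass. Field practice measures these destructively (cut, dry, weigh) or
with coarse instruments — a measuring tape held against the canopy, or a
rising plate meter whose resting height is a compressed-sward statistic. A
hand-held consumer depth camera pointed at the sward from above offers a
non-destructive alternative: fuse a short burst of depth frames into a 3D
model of the plot before and after harvest, and read the traits off the
model.

`swardscan` implements that chain end to end — depth-frame fusion, point
cloud filtering, trait extraction and statistical validation — and, because
no depth-frame or ground-truth archive of this kind is publicly deposited,
drives everything from a synthetic sward generator whose two default
parameter sets emulate the agronomically interesting contrast between a
ryegrass-dominant and a timothy-dominant ley.

## Reconstruction: hashed TSDF fusion with ICP tracking

The fusion state is a truncated signed distance function (TSDF): each voxel
near an observed surface stores a running weighted average of its signed
distance to that surface, clipped to a truncation band. Storage is sparse —
only voxels inside some ray's truncation band are ever allocated — and
addressed by a large-prime XOR hash of the integer voxel coordinates, so
memory scales with observed surface area rather than with the scanned
volume.

Per depth frame the chain is:

1. **Prediction.** Every pixel ray is marched through the voxel grid with an
   integer Amanatides–Woo traversal; the first positive-to-negative sign
   change of the stored distance is interpolated to a predicted range. The
   predicted surface points form the registration target.
2. **Registration.** Point-to-point ICP aligns the new frame's points
   against the prediction (frame-to-model; frame-to-frame is available as a
   flag): nearest-neighbour correspondences with a distance cap and
   reciprocal rejection, then the closed-form SVD (Kabsch) alignment,
   iterated until the residual RMS stabilises. Frames whose final residual
   exceeds 3 cm are skipped and logged rather than integrated.
3. **Integration.** Every voxel crossed by a pixel ray within ± one
   truncation distance of the measured range receives one update. The
   stored value is the signed distance of the *voxel centre projected onto
   the ray*, not of the marching sample — that keeps the stored field an
   exact linear ramp along each ray and removes a quantization error of up
   to a quarter voxel at the extracted surface.

Defaults: voxel size 5 mm (grass-blade scale on a 1 m² plot at tractable
memory), truncation 4 voxels (2 cm), ICP capped at 50 iterations with
relative tolerance 1e-6 on the residual.

**The correspondence cap is 2 cm, not the more usual 5 cm.** On spiky grass
canopies the lateral spacing between blade columns is 3–7 cm; a 5 cm cap
lets correspondences jump between neighbouring blades, which biases each
frame's pose by ~1.5 mm and accumulates to ~15 mm across a ten-frame sweep
on tall plots. Capping below the blade spacing removes the bias (worst-case
pose error drops to under 5 mm). The cap is a user parameter for scenes
with different texture scales.

Surface extraction emits one point per sign change between face-adjacent
voxels, linearly interpolated between voxel centres. Two guards suppress
the classic "veil" artifacts at silhouettes: crossings where either stored
distance sits at the truncation clamp, and crossings whose distance jump
exceeds twice the voxel size (a true distance field cannot change faster
than the voxel pitch between neighbours), are discarded.

## Outlier filtering

The filter computes each point's mean Euclidean distance to its 64 nearest
neighbours and removes isolated points. The classical statistical rule —
remove points above the cloud-wide mean plus one standard deviation of
those per-point means — is the default (`mode = "mean_plus_sd"`, multiplier
adjustable). A second reading, comparing each mean distance to the standard
deviation *alone*, is preserved as `mode = "literal"`: on a perfectly
regular cloud the per-point means are all equal, their standard deviation
is zero, and the literal rule removes everything, which is why it is not
the default. Ties at the k-th neighbour are cut at exactly k in
index-stable order, so the report is deterministic. Clouds with at most k
points are a hard error rather than a silent k reduction.

## Traits

* **Plant height** comes from differencing the pre-harvest and post-harvest
  models: both clouds are rasterized to canopy-top grids (2 cm cells by
  default, half-open, per-cell maximum), differenced per cell and clamped
  at zero. "Average height" is the mean over valid difference cells — an
  areal statistic in the spirit of the plate meter — not a mean over raw
  points. In the synthetic pipeline the two models share the renderer's
  frame-0 anchor; for independently acquired clouds `icp_register()`
  co-registers them first.
* **Alpha-shape volume**: the 3D Delaunay tetrahedralization is built by
  incremental Bowyer–Watson insertion, and tetrahedra whose circumradius is
  below alpha are kept; the volume is their sum. At alpha → ∞ this is the
  convex hull. The default alpha of 0.2 m is the midpoint of the range over
  which the shape transitions from tight to loose on metre-scale canopies;
  it is exposed everywhere as a parameter.
* **DSM solid volume** integrates `max(top − ground, 0) × cell area` over
  the canopy-top raster — the generic solid-object integral that an aerial
  surface-model workflow would compute.
* **Cover area** counts raster cells whose top reaches a threshold
  (default 5 cm above ground).

### Numerical choices in the tetrahedralization

Degenerate inputs (cube corners with face/edge midpoints; voxel-lattice
reconstructions) are cospherical in ways that break naive incremental
Delaunay. The build therefore runs on coordinates scaled to the unit box
and symbolically jittered by 1e-9 with a fixed stream (escalated ×100 on
the rare retry), while **tetrahedron volumes are evaluated on the original
coordinates**. Any valid triangulation of the hull sums to the hull volume,
so the alpha → ∞ limit is exact even for degenerate fixtures — the jitter
affects only which (volume-zero) slivers appear. Circumradii for the alpha
test use the jittered coordinates, where they are always finite.
Reconstructed clouds inherit a near-lattice structure from the voxel grid
that slows the (cavity-based) build by an order of magnitude, so
`extract_traits()` thins clouds to 6000 points by a deterministic stride
before the volume call; on 1 m² canopies the volume estimate is converged
well below that density.

## Validation statistics

`fit_simple_regression()` is ordinary least squares of estimate on ground
truth with Pearson r, R², coefficient standard errors and the residual
standard error (both are reported because either may be meant by a
"standard error of the fit"). `lack_of_fit_test()` is the classical
replicate-based decomposition — pure error within groups of repeated x,
lack of fit against the group-means model — with quadrants inside a plot
supplying the replication. `compare_fields()` tests equality of lines
between the two fields: an F test with 2 numerator degrees of freedom on
the field × (intercept, slope) terms of the pooled model. No
multiple-testing correction is applied: the fits are reported
per-relationship, as a field survey would tabulate them. Plots with fewer
than four quadrants are averaged over what is available and logged, not
dropped.

## The synthetic generator

Each plot is a set of tillers: bases uniform over the 1 m² extent, heights
truncated-normal, and each tiller a short polyline of leaf points leaning
outward quadratically with height (the cheapest geometry that produces
realistic occlusion and canopy-top texture). `bend_fraction` pulls
individual tips toward the plot mean — leaves bending to a "common
height". Ground truth per plot: tape heights as the 95th percentile of tip
heights within a 5 cm probe radius at the four quadrant centres and the
plot centre (a near-max local statistic standing in for a visual tape
reading); the plate meter as the 60th percentile of canopy-top heights in
a centred 0.25 m² footprint (a sub-maximum percentile encodes compression),
clamped at the tallest tape value because a compressed height cannot
exceed the tallest measured tip; dry biomass as a species-specific linear
allometry in mean tip height plus Gaussian noise, clamped at zero.

The two default profiles encode the growth-habit contrast:

| parameter | ryegrass-like | timothy-like |
|---|---|---|
| tiller density (m⁻²) | 2500 | 1100 |
| mean height (m) | 0.45 | 0.60 |
| within-plot height SD (m) | 0.07 | 0.16 |
| bend fraction | 0.75 | 0.10 |
| allometric slope (kg m⁻¹ m⁻²) | 0.06 | 0.85 |
| allometric intercept (kg m⁻²) | 0.34 | 0.03 |
| between-plot height SD (m) | 0.05 | 0.10 |

The ryegrass profile carries its biomass in the intercept (tillering near
the ground) so height barely predicts biomass; the timothy profile carries
it in the slope so height is a strong proxy. One parameter goes beyond the
minimal contract: `plot_height_sd`, the between-plot standard deviation of
the mean sward height. Without it every plot of a field would have nearly
the same mean height (the within-plot mean over ~10³ tillers is almost
constant) and field-level height–biomass correlations would be undefined;
the values chosen (5 and 10 cm) give plot-to-plot spreads typical of
managed leys at anthesis. Within-plot variance values are set to reproduce
the qualitative contrast — nothing in the emulated survey pins them
numerically.

Every random draw derives from one master seed through per-stage
sub-streams (`derive_seed(master, stage, index)`), so adding a stage never
perturbs earlier draws and any stage can be reproduced in isolation.

## The sensing emulation

The renderer holds a canopy-top height field (4 mm cells by default) over
an infinite ground plane and ray-marches each pixel of a pinhole depth
camera: Euclidean range along the ray, bisection-refined at the surface
crossing, Gaussian range noise optional, ranges outside 0.5–4.5 m invalid.
Default intrinsics are a Kinect-class sensor at half resolution, 256 × 212
pixels with a 70° horizontal field of view (≈60° vertical). The default
trajectory is a hand-held top-view sweep at 1.7 m: ten poses 7 mm apart
with a ±1.5° pitch ramp — the small inter-frame motion a 30 fps hand-held
acquisition actually produces. The full-resolution round trip (render →
fuse → compare to the rendered surface) is part of the acceptance suite;
the 20-plot survey runs at 128 × 106 pixels, 6 frames and 8 mm voxels,
which keeps the whole pipeline under a few minutes without changing any
qualitative result.

What the renderer does not emulate: time-of-flight radiometry and
range-dependent noise, motion blur, wind, self-shadowing dropouts, mixed
pixels at silhouettes, and clover as a morphologically distinct species.
Consequences: passing the round-trip criteria shows the *geometry* of the
chain is right (registration, integration, extraction, traits), not that
it is robust to a real sensor's artifact spectrum.

## Problem sizes and budgets

The shipped analyses use: 20 000-point clouds for the alpha-shape oracle;
one full-resolution ten-frame fusion round trip; 2 × 10 plots at survey
resolution for the field contrast; 1000 simulation replicates for each
null-calibration check and 500 for slope-CI coverage. These sizes were
chosen so each check is statistically decisive yet the whole suite runs on
a laptop-class single core in minutes.

## Known limitations

* Pose tracking has no loop closure; drift over long trajectories is
  unbounded. The intended acquisition is a short sweep.
* The projective TSDF stores distance along the ray, not true Euclidean
  distance; on surfaces slanted away from the rays the zero crossing is
  slightly biased. Near-nadir viewing of mostly-horizontal canopies keeps
  this below the voxel size.
* The alpha-shape build is exact-arithmetic-free; inputs engineered to be
  adversarially degenerate beyond the jitter's resolution can still fail
  (they raise an error rather than returning a wrong volume).
* The literal reading of the outlier rule is preserved for comparison but
  is not viable on regular clouds (see above).
* Biomass enters only through the generator's allometry; the package
  validates *proxies* (height, volume) against biomass, it does not
  predict biomass from reconstructions.
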