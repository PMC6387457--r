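# swardscan

On-ground 3D characterization of grassland sward plots from depth-camera
frames: TSDF fusion with ICP pose tracking, statistical outlier filtering,
and extraction of the canopy traits a pasture survey needs — plant height
by pre/post-harvest model differencing, cover area, alpha-shape volume and
DSM solid volume — validated against tape, rising-plate-meter and
dry-biomass ground truth with simple linear regression, lack-of-fit tests
and between-field ANOVA.

The package targets the survey design used in grass-ley field work: two
fields of contrasting botanical composition (ryegrass-dominant vs
timothy-dominant), ten 1 m² plots per field, each plot measured on four
quadrants plus the centre, then cut, dried and weighed. Because no public
archive of such depth-frame data exists, a first-class synthetic canopy
generator emulates the whole acquisition — per-plot canopy and stubble
clouds, depth-frame sequences from a Kinect-class camera model, and the
manual measurements — so every stage is testable end to end.

## The methods in brief

* **Fusion.** A sparse truncated-signed-distance volume (5 mm voxels,
  2 cm truncation) addressed by a large-prime XOR voxel hash; per frame,
  ray-cast model prediction (Amanatides–Woo grid traversal), point-to-point
  ICP with SVD alignment, reciprocal rejection and a 2 cm correspondence
  cap, then a weighted running-average signed-distance update along every
  pixel ray. The surface is extracted at signed-distance zero crossings.
* **Filtering.** A point is an outlier when its mean distance to its 64
  nearest neighbours exceeds the cloud-wide mean + 1 SD of those
  distances (the literal "exceeds the SD alone" reading is kept as a
  mode for comparison).
* **Traits.** Height raster differencing (pre − post, clamped at 0),
  cover area above a threshold, the 3D alpha-shape volume (Delaunay
  tetrahedra with circumradius < α, default α = 0.2 m; α → ∞ recovers the
  convex hull) and the solid volume under the canopy-top raster.
* **Validation.** OLS of estimates on ground truth with r, R² and
  standard errors; replicate-based lack-of-fit F tests (quadrants within
  plots replicate the plot-level x); equality-of-lines F test between
  fields.

## Worked example

```r
library(swardscan)

# one synthetic timothy-dominant plot with its ground truth
tr <- generate_canopy(plot_spec("demo", timothy_profile(), seed = 11))
tr
#> ground_truth_plot 'demo': 15400 canopy pts, 1213 stubble pts
#>   tape 1.017-1.128 m, plate 0.868 m, biomass 0.791 kg/m2

# render a hand-held sweep and fuse it
intr   <- camera_intrinsics()          # 256 x 212 px, 70 deg FOV, 0.5-4.5 m
traj   <- sweep_trajectory(10)
frames <- render_depth_frames(tr, traj, intr, noise_sd = 0)
rec    <- reconstruct(frames, intr, voxel_size = 0.005)
nrow(rec$cloud)
#> [1] 242449

# filter, anchor into the plot frame, and extract the trait record
pre <- remove_outliers(rec$cloud)$cloud          # 64-NN outlier rule
pre <- crop_cloud(transform_cloud(pre, traj[[1]]))
extract_traits(pre, tr$stubble, plot_id = "demo")
#>   plot_id max_height_m mean_height_m cover_m2 alpha_volume_m3 dsm_volume_m3
#> 1    demo     1.199371     0.7865315   0.8484       0.5925567     0.7105697
```

The record reads: tallest canopy column 1.20 m above the stubble, areal
mean height 0.79 m, 0.85 m2 of the plot covered above the 5 cm threshold,
an alpha-shape (α = 0.2 m) volume of 0.59 m3 and a solid volume under the
canopy-top raster of 0.71 m3 — a tall, fairly open timothy-like sward.

The full survey (2 fields × 10 plots, fusion on) is the pipeline:

```r
res <- run_pipeline(run_config(seed = 1, plots_per_field = 10,
                               out_dir = "results/pipeline"))
res$stats$timothy$biomass_height$r_squared    # 0.875: height predicts biomass
res$stats$ryegrass$biomass_height$r_squared   # 0.092: ... only for timothy
res$stats$field_contrast$p_value              # 3.1e-11: the fields differ
```

Heights track the tape measurements closely (plot-level R² 0.998 and 0.93
for the ryegrass-like and timothy-like fields in this run, quadrant-level
0.988 and 0.82), and the height–biomass relationship separates the two
growth habits: tall-growing timothy yields R² ≈ 0.88, tillering ryegrass
R² ≈ 0.09.

The same steps are available as a narrated workflow under `analysis/`
(`01_simulate.R` … `05_stats.R`), each writing its tables under
`results/`.

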