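# stereomire

A fully synthetic testbed for **microscopic stereo surface reconstruction
under adaptive projected dot patterns** — the reconstruction approach used in
ENT/skull-base surgery research, where a zoomable stereo operating microscope
is paired with a near-infrared pattern projector because anatomy (bone,
tissue, an ear model) is too homogeneous for block-matching stereo on its
own.

The package simulates the entire measurement chain and makes every stage
testable against exact ground truth:

* an ear-like phantom surface (90 x 40 mm) with four multimodal fiducial
  markers whose registration targets sit exactly 1 mm beneath the marker
  faces, plus a region-of-interest (ROI) cuboid over the central anatomy;
* a two-camera microscope model (zoom levels 1.1x–1.5x, focal length linear
  in zoom, verged 24 mm baseline) and an 800 x 600 pattern projector, with
  z-buffer rendering, Phong shading, projector shadow mapping and sensor
  noise;
* Zhang-style stereo calibration from synthetic 9 x 5 checkerboard
  observations (3 mm squares, 19 pose pairs per zoom), Bouguet-style
  rectification, and a per-zoom JSON lookup table;
* semi-global block matching (SAD block 3, 4/8-path aggregation, P1/P2
  penalties, left-right check, uniqueness, texture and speckle filters) and
  triangulation to metric point clouds;
* Horn's closed-form absolute orientation on the fiducials and a
  closest-point error metric: a seeded 5000-point subset of the ROI-cropped
  reconstruction scored by nearest-neighbor distance to the dense reference
  cloud (both RMSE and mean absolute distance are recorded);
* a Gaussian-process Bayesian optimizer (RBF + output-scale kernel, expected
  improvement, 10 random initial evaluations, exhaustive acquisition over
  the integer box d ∈ [1,10], s ∈ [2,16]) that tunes the projected dot size
  `s` and spacing `d` per zoom level;
* an experiment driver reproducing the 4-illumination x 5-zoom x 10-repeat
  comparison design (200 reconstructions) with per-record seed replay,
  summary tables and Z-difference heat maps.

## Worked example

```r
library(stereomire)

scene <- generate_phantom(seed = 0, complexity = 1)
rig   <- make_zoom_rig(1.3, rig_config("desk"))

# calibrate from synthetic checkerboard corners (19 noisy pose pairs)
obs   <- render_calibration_set(rig, board_spec(), n_poses = 19,
                                seed = 0, corner_noise_px = 0.2)
entry <- calibrate_stereo(obs, zoom = 1.3, estimate_distortion = FALSE)
entry
#> <calibration_entry> zoom 1.30, f_rect 974.8 px, baseline 23.971 mm, rms 0.2744 px

# render a stereo pair under the adaptive dot pattern and reconstruct
illum <- illumination_config("adaptive_pattern",
                             pattern = generate_dot_pattern(pattern_params(3, 4)))
pair  <- render_stereo_pair(scene, rig, illum, seed = 1)
rng   <- disparity_range(entry, 165, 235)
cloud <- reconstruct_mire(pair$left, pair$right, entry,
                          sgbm_params(min_disparity = rng$min_disparity,
                                      num_disparities = rng$num_disparities,
                                      n_paths = 4))

# register via the fiducials and score inside the ROI
gt      <- sample_ground_truth_cloud(scene, 40000, seed = 0)
targets <- localize_fiducials_3d(cloud, scene)
reg     <- horn_align(targets, fiducial_target_points(scene))
reconstruction_error(cloud, gt, reg, scene$roi, seed = 0)
#> <rmse_result> rmse 0.6971 mm, mean |d| 0.5736 mm (5000 of 6752 ROI points)
```

The reconstruction error of ~0.7 mm is the root-mean-square closest-point
distance between a 5000-point subset of the registered reconstruction and
the dense ground-truth surface, inside the ROI — the headline quality metric
throughout the package. The full comparison experiment
(`run_experiment(experiment_config(), master_seed = 0)`) reproduces the
qualitative finding the method rests on: adaptive-pattern illumination beats
diffuse environmental light and the saturating microscope spot at every zoom
level.

The per-zoom pattern optimization itself:

```r
cfg <- experiment_config(zooms = 1.3, calibration = "true")
tab <- build_zoom_lookup(cfg, master_seed = 0)   # 10 random + 15 EI rounds
tab                                              # zoom, best d, s, error_mm
```

A thin CLI over the same functions lives at `inst/cli/stereomire.R`
(subcommands `phantom`, `pattern`, `calibrate`, `reconstruct`, `optimize`,
`experiment`, `report`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end pipeline from
scratch — phantom generation, per-zoom calibration, rendering under all four
illumination modes, matching, registration and scoring on a reduced
comparison grid — prints the per-cell summary table and writes the results
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/stereomire-methods.Rmd`) describes the
simulation model and its assumptions, every tunable parameter with units and
defaults, the numerical choices, what the synthetic world does and does not
emulate, and known limitations.
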