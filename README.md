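# gammadex

Marker-based instrument tracking and movement-dexterity analysis for
robot-assisted radioguided surgery.

When a gamma-probe rides on (or is grasped by) a robotic laparoscopic
instrument, the surgeon's skill shows up in how the instrument tip moves:
how far it travels, how straight and smooth the path is, and how quickly
the search converges on a radioactive target. `gammadex` implements the
full desk-side analysis chain for such experiments:

1. **Camera geometry** — a pinhole model with (k1, k2, p1, p2) distortion
   and planar-checkerboard calibration (Zhang initialization +
   Levenberg–Marquardt refinement of intrinsics, distortion and per-view
   extrinsics).
2. **Marker tracking** — segmentation of a cyan rectangle and a yellow
   three-ring marker by hue/saturation/value, sub-pixel measurement
   (coverage-weighted centroids; corner refinement by total-least-squares
   line fits to coverage-shifted edge pixels), and monocular pose
   estimation of the instrument tip from the known marker geometry. Depth
   comes from the projected marker scale; the ring triplet's projected
   spacing encodes depth when the rectangle rolls out of view.
3. **Trajectory processing** — out-of-view gap flagging, linear
   interpolation of short gaps, and a running median filter.
4. **Movement features** — per trial: completion time, path length,
   straightness index (net displacement / path length), angular
   dispersion (mean resultant length `R = |Σ uᵢ|/n` of unit step
   directions), and trial medians of per-frame speed `|v|`, acceleration
   `|a|`, curvature `κ = |v × a| / |v|³` and jerk `|da/dt|`; paired-samples
   t tests between conditions.
5. **Occupancy density maps** — percentage of trial time per 1-cm cell
   (%s/cm³ in 3D, %s/cm² in 2D) with color overlays, plus focus summaries
   (maximum cell percentage, Shannon entropy).
6. **Dexterity score** — an L2-penalized logistic regression of trial
   success on the movement features (plus final tip-to-target distance),
   whose sigmoid output serves as a continuous per-trial skill score.
7. **Synthetic data** — a renderer that draws the markers at known poses
   (so tracking can be validated against exact ground truth), a simulator
   of the ten-movement pick/identify/collect phantom exercise for the
   tethered (`dropin`) vs integrated (`clickon`) probe designs, and a
   simulator of guided/unguided target searches under a 40-s failure rule
   with a Poisson counting-probe model
   (rate = background + sensitivity · activity · (10 mm/d)²).

## Worked example

```r
library(gammadex)

# render a frame at a known pose, then track it back
cam  <- default_camera()
pose <- facing_pose(c(5, -3, 150), roll_deg = -30)
fr   <- render_marker_frame(cam, pose)
tp   <- estimate_tip_position(
  classify_marker(segment_markers(fr$image, default_marker_specs()),
                  default_marker_specs()),
  cam, default_marker_specs())
sqrt(sum((tp$position_cam - fr$tip_mm)^2))
#> [1] 0.005185434       # tip recovered to well under 0.1 mm

# paired phantom study: probe designs on the same simulated operators
ph <- run_phantom_study(run_config(base_seed = 1))
ph$movement_counts
#> $dropin
#> [1] 10
#> $clickon
#> [1] 6
#> $reduction_percent
#> [1] 40

# guided vs unguided target search under the 40-s rule (5 operators)
sr <- run_search_study(run_config(base_seed = 3))
unlist(sr$rates)
#>         palpation       radioguided difference_points             ratio
#>                20               100                80                 5
```

The movement counts say that carrying the detector on the instrument
removes the four probe-handling movements of the ten-movement exercise (a
40% reduction); the completion rates compare the simulated operators'
target-finding with and without the count-rate guidance.

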