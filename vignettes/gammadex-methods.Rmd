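---
title: "Tracking and dexterity analysis for gamma-probe guided robotic surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and dexterity analysis for gamma-probe guided robotic surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammadex)
```

## The problem

In radioguided laparoscopic surgery a gamma-emitting tracer marks the
target tissue and a counting probe tells the surgeon, through its count
rate, how close the instrument is to the target. Two probe designs differ
in workflow: a tethered probe must be picked up, carried, returned and
dropped by the grasper, while an integrated probe travels on the
instrument itself. The behavioural consequences — fewer movements, shorter
paths, straighter trajectories, higher target-finding rates — are what
this package measures, from endoscopic video to per-trial statistics.

The pipeline has three layers: (i) recovering the instrument-tip
trajectory in millimetres from video of two fiducial markers, (ii)
condensing each trial into eight movement metrics and occupancy density
maps, and (iii) classifying trial success from those metrics with a
logistic model whose sigmoid output acts as a dexterity score. A
synthetic-data layer generates all inputs with known ground truth, which
is how the pipeline is validated end to end.

## Camera model and calibration

The endoscope is a pinhole camera with focal lengths (fx, fy) and
principal point (cx, cy) in pixels, plus a four-coefficient distortion
(k1, k2 radial; p1, p2 tangential). Higher radial orders are deliberately
omitted: at a typical 70° field of view they are indistinguishable from
noise in checkerboard residuals, and every operation that needs the
inverse mapping (undistortion) converges in a few fixed-point iterations
at this model order.

`calibrate_intrinsics()` follows the standard planar-target scheme:
per-view homographies give closed-form intrinsics via the absolute-conic
constraints, then all parameters including per-view extrinsics are
polished by Levenberg–Marquardt on the reprojection error. On noiseless
synthetic corners the intrinsics are recovered to machine precision; with
0.5 px corner noise over ten views the RMS reprojection error stays below
1 px and focal lengths within ~1%. Fewer than three views, or collinear
corners, are rejected — the closed-form step is singular there.

The default calibration target in the tests is a 15-mm checkerboard seen
in 8–10 views at 26–42 cm; neither the square size nor the view count is
critical, and both are plain arguments.

## Markers and tip pose estimation

Two markers ride on the instrument, mounted on different faces of the
shaft so that at least one faces the camera at any roll angle:

* a cyan rectangle (default 20 × 10 mm), whose four corners pin down the
  full six-degree-of-freedom pose from one view, and
* a yellow triplet of equally spaced rings (default 8 mm spacing), whose
  projected spacing encodes depth when the rectangle rolls edge-on.

Default hue windows are cyan 0.45–0.55 and yellow 0.12–0.20 (HSV, 0–1
scale) — chosen not to overlap and to be far from tissue hues; they are
configurable per marker, as are all dimensions, because physical marker
sizes vary between instrument builds.

Segmentation thresholds in HSV, cleans the masks with a 3×3 morphological
opening and closing (EBImage), and labels connected regions. The
classifier then re-measures each candidate region on a *soft coverage
map*: pixel colors are projected onto the axis between the region's
interior color and the local background color, giving each pixel its
fractional marker coverage (pixels of other marker classes are excluded
from the background estimate). Two sub-pixel devices follow:

* **Ring centres** are coverage-weighted centroids. For a filled or
  annular marker the weighted centroid of an anti-aliased image patch
  localizes far below one pixel.
* **Rectangle corners** come from intersecting total-least-squares line
  fits to edge pixels, each shifted onto the edge by inverting the exact
  covered-area function of a unit pixel cut by a straight edge (linear in
  the middle band, quadratic in the corner-triangle bands of the edge
  normal). Pixels near the corners, where coverage mixes two edges, are
  excluded; the reference quadrilateral is iterated three times so the
  side assignment converges under perspective. If an edge happens to sit
  exactly on a pixel boundary (so no partially covered pixels exist), the
  fully covered boundary row is used instead — the inversion formula then
  places the edge half a pixel outward, which is exact in that case.

Pose estimation treats the two marker types differently. The rectangle's
four corners give a plane-to-image homography whose decomposition
initializes a Levenberg–Marquardt pose refinement. Two discrete
ambiguities are kept as explicit candidates rather than resolved locally:
the 180° correspondence ambiguity of a rectangle, and the classic planar
two-fold tilt ambiguity (both reproject essentially exactly). The ring
triplet is solved globally by a one-dimensional scan over the first ring's
depth — given that depth, the second centre follows from the known
spacing (a quadratic with two branches) and the third is determined by
collinearity, so the misfit is a function of one variable whose local
minima are polished by Levenberg–Marquardt; the reversed ring order gives
its own direction ambiguity.

Ambiguities are resolved by *cross-marker consistency*: a rectangle pose
candidate determines the full instrument frame and therefore predicts
where the three ring centres must appear in the image; the wrong 180° twin
misplaces them by the tip-offset scale (hundreds of pixels), so the
measured centroids decide. With only one marker visible, the previous
frame's tip serves as the prior; a lone ring triplet with no prior is
reported invalid rather than guessed, per the missing-data contract. When
both markers resolve, the one with the lower reprojection residual wins,
with the residual floored at 0.05 px (the expected sub-pixel measurement
noise) so that the nearly exactly determined ring fit — six measurements,
five line parameters — cannot win on an artificially tiny residual; ties
go to the rectangle, which carries more constraints.

The tracking output frame follows the image-plane convention: x and y
parallel to the image plane with the origin on the optical axis, y up,
and z the distance from the camera, all in millimetres; the conversion
from the internal camera frame (y down) happens once, at output, and is
recorded in the trajectory CSV header.

### Accuracy at the working distance

The synthetic working range is 12–18 cm from a 960 × 540, fx = 700 px
endoscope (≈ 69° field of view) — the scale at which a 20-mm marker spans
roughly 80–120 px. An error budget at this scale says corner measurements
must be good to a few hundredths of a pixel for 0.1-mm tip accuracy, which
drove two renderer/measurement design choices: anti-aliased rasterization
with *jittered stratified* subsampling (an aligned subsample grid
quantizes coverage identically along axis-aligned edges and biases whole
line fits by the same fraction of a stratum), and the exact coverage
inversion above. Under these conditions the render→track round trip
recovers the tip to well under 0.1 mm across random working-range poses,
and a 100-frame sweep tracks with per-axis RMS below 0.2 mm. Ring-only
estimates are a few tenths of a millimetre — the annulus centroid carries
a small perspective bias that the line model does not remove — which is
why the rectangle is preferred whenever both markers resolve.

## Trajectory processing

Raw tracks are cleaned in the order: flag invalid runs, interpolate, then
median-filter. Interior gaps up to `max_gap_s` (default 1 s) are filled
per axis by linear interpolation and marked `interpolated`; leading and
trailing gaps cannot be interpolated and are trimmed; longer interior
gaps split the track into sub-tracks, and the downstream default is to
analyse the longest sub-track (the choice is recorded in the processing
log). The median filter (default 5 frames, shrinking symmetrically at the
edges) removes isolated tracking spikes and is a fixed point on monotone
segments. Both parameters are exposed because neither has a principled
universal value; the defaults correspond to 1 s of occlusion and 0.2 s of
smoothing at 25 Hz.

The frame rate defaults to 25 Hz throughout — a standard video rate; all
operations take fps as data, not as an assumption.

## Movement features

Eight metrics summarize a trial: completion time, path length,
straightness index, angular dispersion, and the trial medians of
per-frame speed, acceleration, curvature and jerk. Derivatives use
central differences at the uniform sampling step with one-sided stencils
at the ends; because a one-sided stencil contaminates the first and last
three frames of the third derivative, boundary frames are excluded from
the medians. Curvature `|v × a|/|v|³` is set to zero below a speed
threshold `v_eps = 1e-3` mm/s, where the ratio is numerically meaningless.

Two of the eight have competing definitions in the movement-analysis
literature, so the package commits to one and isolates it behind the
feature interface: *angular dispersion* is the mean resultant length of
the unit step-direction vectors in 3D (1 = all steps aligned, 0 =
isotropic), and *smoothness* is the per-frame jerk magnitude, aggregated
by the trial median like the other per-frame features. Because published
phantom tables using other definitions are not numerically comparable,
the test suite validates these metrics against closed forms (circular
motion, cubic paths, isotropic steps) and invariances — all eight are
invariant to rigid motions, scale the expected way under spatial
rescaling, and path length and straightness are time-reversal invariant —
rather than against any published means.

Condition comparisons use the classical paired-samples t test per metric
on per-subject differences, reported raw without multiple-testing
correction across the eight metrics (mirroring common practice in these
small studies; the limitation is noted here deliberately). Zero-variance
differences are reported with exact p (0 or 1) and a warning rather than
NaN.

## Occupancy density maps

The occupancy map counts each sample as 1/fps seconds in its half-open
1-cm cell: %s/cm³ in 3D, and its z-marginal %s/cm² on the image plane.
Sample-point binning (rather than path-segment integration) matches the
per-frame data model. Samples outside the grid go to an explicit
out-of-grid bin so the total is always 100%. The grid origin snaps to a
multiple of the cell edge below the trajectory's bounding box; cell edge
10 mm is the unit that makes the percentages per cm³. Focus statistics
are the maximum cell percentage and the Shannon entropy over occupied
cells; refining the grid can only increase entropy, and a focused search
(most of its time at the target) has low entropy and a maximum cell at or
adjacent to the source's cell — "adjacent" because a 10-mm detection
radius legitimately parks the tip in a neighbouring 1-cm cell. The 2D
overlay maps percentages through a monotone blue–red ramp normalized to
the per-trial maximum (a per-cohort normalization is equally defensible;
per-trial is the documented default), with 0% cells fully transparent.

## Dexterity scoring

The design matrix holds the eight features plus, when a target location
is known, the distance from the trajectory endpoint to the target — a
single interpretable "final instrument position" covariate appropriate
for a ten-trial problem. Columns are standardized (the model stores the
standardization, making scores invariant to affine rescaling of raw
features); constant columns are dropped with a warning. The fit maximizes
the L2-penalized Bernoulli log-likelihood by damped Newton iterations to
a 1e-8 gradient tolerance — deterministic, no stochastic optimizer. The
default penalty (1.0) exists because n ≈ 10 trials with 9 covariates is
otherwise separable more often than not; with the penalty at zero,
separation is detected (a weight vector that classifies everything
correctly while saturating proves separability) and reported as an error
advising a penalty. Evaluation in the tiny-n regime uses leave-one-out
refits. Scores are ranked descending with ties broken by trial id.

## The synthetic-data layer

The renderer draws both markers over a desaturated background with
coverage-based anti-aliasing (12 × 12 jittered stratified subsamples per
pixel) and returns the exact 3D tip implied by the pose — the ground
truth for every tracking test.

The phantom simulator walks the scripted pick/identify/collect exercise:
ten movements for the tethered probe; six for the integrated probe, which
skips the probe pick-up at home, the return transit, the probe drop, and
the second transit out — the detector travels on the instrument. Segment
durations come from a nominal transit speed and handling dwell that slow
with decreasing skill (40 mm/s and 1.5 s at skill 1), snapped to the
frame grid so that at skill 1 the trajectory is exactly the anchor
polyline. Imperfection enters as an AR(1)-correlated Gaussian tremor
perpendicular to travel and a smooth mid-segment detour, both scaled by
(1 − skill); the AR correlation (0.85 at 25 Hz) makes tremor
band-limited rather than white, which is what keeps simulated curvature
and jerk in a realistic range.

The search simulator emulates the blinded target-finding exercise under
its 40-s failure rule. Both conditions inspect a sequence of positions at
a small standoff below the abdominal-wall plane. Unguided (palpation)
search is a correlated random walk of inspection points with a palpation
dwell at each. Guided search listens to the probe continuously: the 0.5-s
moving-average count rate is tracked frame by frame (attributed to the
window-centre position to correct for motion smearing, with a gentle
decay so a lucky Poisson fluctuation cannot pin the search), the loudest
reading is inverted through the inverse-square law into a
remaining-distance estimate, and the next inspection point is drawn at
that scale around the loudest position. When an inspection implies the
source is inside the detection radius the operator declares the find and
holds the probe still; after a success the probe is held on the target
for a 3-s confirmation that is part of the recorded trajectory but not of
the detection time. An earlier design estimated the count gradient only
by finite differences between inspection points, as a literal reading of
"bias the walk up the count gradient" would suggest; it proved
non-convergent under Poisson noise — close passes during transits went
unheard and the finite-difference direction oscillated — and was replaced
by the continuous-listening form, which is also closer to how surgeons
actually use the audible readout.

Success is behavioural, so it needs an operational definition: the tip
must stay within 10 mm of the source for 1 s before the 40-s limit.
Both numbers are arbitrary but fixed and configurable. The probe model —
1000 counts/s at 10 mm per unit activity (solid angle × emission ×
efficiency of a sub-MBq source at close range), 5 counts/s background,
90° acceptance half-angle for a weakly collimated tethered probe — makes
the count gradient informative across the 14 × 10 cm workspace, which is
the design requirement for the guidance signal. Under these defaults the
guided success rate exceeds the unguided one by well over 30 percentage
points across 200 paired seeds, guided detection times fall in roughly
the 3–35 s range, and guided searches show lower occupancy entropy than
their unguided twins in ~95% of seed pairs.

What the simulators do *not* emulate matters for interpreting green
tests: no tissue appearance or illumination changes, no motion blur or
rolling shutter, no marker occlusion by anatomy, no human learning across
trials, and flat (not cylindrical) ring markers. Passing the render→track
round trip therefore validates the geometry and measurement chain, not
robustness to clinical image conditions; the behavioural simulators
validate the analysis pipeline's discrimination, not any claim about real
surgeons.

## Problem sizes and defaults used in validation

The test suite validates tracking on 50 random working-range poses and
100-frame sweeps at 960 × 540, the search comparison on 200 paired
seeds, the skill-recovery check on a 16-operator simulated cohort, and
calibration on 8–10 views of a 63-corner board — sizes chosen so each
statistical check has clear margin while the full suite stays fast. The
canonical seed for deterministic fixtures is 1; simulation-property tests
loop over consecutive seeds rather than cherry-picking.

## Known limitations

* Monocular depth comes entirely from marker scale, so depth accuracy
  degrades quadratically with distance and linearly with marker size;
  beyond ~25 cm the 0.1-mm regime is out of reach at this resolution.
* The ring-triplet path carries a perspective centroid bias (no
  annulus-shape correction is applied), making it a hand-off fallback
  rather than an equal partner of the rectangle.
* The logistic score is in-sample by default; with n ≈ 10 trials,
  leave-one-out accuracy is the only honest generalization estimate, and
  even it is noisy.
* Simulated completion rates depend on the search-policy parameters;
  they are modelling choices, and only the printed per-fellow outcome
  table gives the empirical rates.
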