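---
title: "Geometry and simulation of laser-crosshair registration for mixed-reality neuronavigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and simulation of laser-crosshair registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosshairsim)
```

## The registration problem

Mixed-reality neuronavigation (MRN) overlays holograms of a patient's
anatomy — segmented from a CT or MRI reference image — onto the patient as
seen through an optical head-mounted display. The overlay is only useful if
the transform between the reference image coordinate system (RICS) and the
headset's world frame is known accurately. Conventional MRN registration
recovers that transform by having the user align virtual objects or probe
fiducials, which is slow and strongly user-dependent.

The alternative modelled by this package transfers the scanner's own frame
to the operating room with a *laser crosshair simulator*: a rigid rack
carrying two laser emitters whose four fan planes span three mutually
orthogonal planes, replicating the gantry's laser positioning planes. At
acquisition time the gantry lasers are marked on the patient's skin; in the
OR the simulator is posed until its projected crosshairs coincide with
those marked lines, at which point the simulator's frame (SCS) reproduces
the scanner frame, and with it the RICS.

## Coordinate frames and the transform chain

Six right-handed frames are involved, all in millimetres:

| frame | meaning |
|---|---|
| `WORLD` | the headset's SLAM world frame |
| `HMD` | the headset itself |
| `VCS` | virtual frame anchored to the tracked image target on the rig |
| `SCS` | simulator frame spanned by the three laser planes |
| `RICS` | reference image frame fixed by the gantry lasers at acquisition |
| `SCANNER` | the scanner's mechanical frame |

`rigid_transform(source, target, rotation, translation)` stores a proper
rigid map (columns convention, `p' = R p + t`); `compose(first, second)`
applies `first` then `second`. The world-to-scanner transform resolves as
the five-factor product

```
T_WSc = T_SSc . T_RS . T_VR . T_HV . T_WH
```

with `T_WH` from SLAM, `T_HV` from image-target tracking, `T_VR` the
extrinsic calibration, `T_RS` the intrinsic calibration, and `T_SSc` the
deployment step. `chain_world_to_scanner()` resolves it from a
`frame_graph`; with every link correct the mapped hologram fiducials
coincide with their physical counterparts exactly, which is the pipeline's
central correctness property and is asserted to below 1e-6 mm in the test
suite.

Design choices worth recording: transforms are stored as homogeneous 4x4
matrices (uniform composition and inversion); rotations are parameterized
for constructors and optimizers as rotation vectors (axis-angle, radians),
which is minimal and singularity-free near the identity where all the
calibration and deployment corrections live; constructors re-project
near-orthogonal matrices (within 1e-6) by polar decomposition and reject
anything worse, including reflections. Under perfect deployment we take
`T_SSc` to be the identity — the source material treats the simulator as
reproducing the scanner frame outright and never assigns this link a fixed
offset; any residual deployment misfit is reported alongside the pose
rather than silently absorbed.

## Laser geometry and projection

The rig model (`build_rig()`) places a top emitter 400 mm above and a side
emitter 400 mm lateral of the SCS origin; the mounting distances are
configurable metadata and do not affect plane geometry. Each emitter fans
two planes that contain its boresight. The top emitter fans the sagittal
(normal x) and coronal (normal y) planes, the side emitter the coronal and
axial (normal z) planes; the shared coronal plane is stored once, so a
calibrated rig spans exactly three planes intersecting in the SCS origin.
Miscalibration is modelled as a rotation of each fan normal about its
emitter's boresight (four angles), which preserves the physical constraint
that a fan always contains its emitter axis.

Projection (`project_crosshair()`, and `mark_reference_lines()` for the
scanner side, which shares the same engine) intersects each plane with a
triangulated surface by edge–plane crossings chained across adjacent
triangles — keying intersection points by the mesh edge they lie on makes
the chaining exact, with vertex ties broken by a 1e-9 mm nudge. Curves are
clipped to the laser-visible side: a vertex is kept when its outward
surface normal has positive dot product with the direction to the emitter
(sagittal lines lit from the top emitter, axial from the side, coronal
from either). Full ray-cast occlusion is deliberately omitted: the
visibility rule is cheap, deterministic, and reproduces the lines actually
drawable on the upper and lateral scalp. Curves are resampled at a 0.5 mm
default step and arcs shorter than twice the step are dropped.

Curve agreement is scored by `curve_misfit()`: the symmetric mean
closest-point distance between same-label polylines. The mean (rather than
Hausdorff) distance gives the optimizers a smooth landscape;
`curve_hausdorff()` is available as a stricter diagnostic.

## Calibration with the sphere

The calibration sphere (default radius 60 mm) carries three great-circle
arcs on mutually orthogonal sections through its centre and three
small-circle arcs on parallel sections at a common offset `d`. Solid
geometry gives two useful facts, both verified numerically in the tests:
the three small circles are pairwise tangent on the sphere exactly at
`d = R/sqrt(2)` (the number of intersection points of two orthogonal small
circles is 2, 1, 0 for `d` below, at, above that value — the roots of
`z^2 = R^2 - 2 d^2`), and any per-colour choice of great or small section
yields three mutually orthogonal planes, so there are exactly 8 orthogonal
combinations: the all-great primary calibration position (PCP) and 7
secondary positions (SCPs). Arcs are represented as full circles for
residual computation — the physical arc extents are not specified anywhere
authoritative, and full circles are a strictly stronger constraint with
simpler mathematics.

**Intrinsic calibration** (`intrinsic_calibrate()`) recovers the four fan
angles by minimizing the mean projected-arc-to-marked-arc distance at the
PCP with a Nelder-Mead simplex, finished by two coordinate line-search
sweeps (the four angles decouple in the PCP residual, so the line searches
converge essentially to machine precision). The seven SCPs are used purely
as held-out verification, mirroring the physical procedure of adjusting
the laser screws at the PCP and then checking the other positions; the
procedure errors out if any of the eight residuals exceeds 0.01 mm.
Recovery of a known 2-degree fan tilt is accurate to well below 0.05
degrees in the tests.

**Extrinsic calibration** (`extrinsic_calibrate()`) simulates aligning the
virtual calibration sphere with the physical one at the PCP. The physical
great circles (RICS) are observed through the unknown true `T_VR` in VCS
coordinates, sampled at 500 points per circle (optionally with isotropic
noise), and the candidate transform is fitted with Levenberg-Marquardt on
the analytic point-to-circle distances — the nearest point on a circle has
a closed form, so no correspondence search is needed. We solve for `T_VR`
and derive `T_VS = T_RS . T_VR`; whether the physical procedure pins down
`T_VR` or `T_VS` directly is ambiguous, but the two are equivalent given
the intrinsic calibration, and `T_VR` is the quantity the chain consumes.
Arcs are keyed by role (sagittal/coronal/axial) rather than colour, since
the physical and virtual spheres use different colour schemes. Noiseless
recovery from a (10 mm, 5 degree) offset is accurate to below (0.01 mm,
0.01 degree); 0.2 mm per-point arc noise degrades translation recovery to
about 0.01–0.5 mm depending on draw.

## Deployment and the degrees-of-freedom argument

`deploy_simulator()` is the algorithmic counterpart of the manual
alignment step: a 6-DOF search over (rotation vector, translation) of the
rig pose minimizing the mean distance from marked-line points (thinned to
400 for the objective) to the projected curves. Up to 8 seeded
Nelder-Mead starts are jittered around the initial pose, each polished by
Levenberg-Marquardt on the full residual vector, with an early exit as
soon as the misfit is below 0.05 mm; a best misfit above 0.5 mm raises a
deployment-failure error rather than returning a bad pose. With the
default head fixture, recovery from a (5 mm, 5 degree) initial error
lands within 1e-7 mm of the true scanner pose — far inside the (0.1 mm,
0.1 degree) target — usually on the first start.

Why this works is a curvature story. On a flat plate a single projected
crosshair leaves translation along the emitter boresight (and the two
tilts) unconstrained — the projected lines do not move — while in-plane
translations and the in-plane rotation are pinned.
`deployment_information()` exposes this as a Gauss-Newton information
matrix built from one-sided finite differences of the residuals (one-sided
because at the optimum the unsigned distances sit at a kink where central
differences cancel); on the plate its boresight direction is an exact
null vector, on a curved head all six eigenvalues are solidly positive.
`curvature_sensitivity()` quantifies the same effect parametrically: on
paraboloid patches `z = (x^2 + y^2) / (2 rho)` (aperture 80 mm), a 1
degree rig tilt displaces the projected cross by about 0.09 mm at
`rho = 40` mm versus about 0.03 mm at `rho = 120` mm, decreasing in
`rho` and, in the small-angle regime, linear in the tilt — flatter
surfaces constrain the pose less.

## The measurement protocol and its statistics

`run_protocol()` reproduces the nested accuracy protocol: per
registration an optional rigid bias is drawn once (isotropic Gaussian
translation), then each session probes every marker with independent
isotropic Gaussian perception noise; the default shape is 3 registrations
x 3 sessions x 6 markers = 54 points. The per-point error is the
Euclidean distance between reference and probed positions, with signed
per-axis components retained; `summarize_tre()` reports mean, sample
(n-1) SD, min, max — overall and by registration and marker — the
fraction of points strictly below a clinical cutoff (default 5 mm), and
per-axis RMSE, since the aggregate error is quoted both ways in the
field. `anova_oneway()` (a thin wrapper over the classical fixed-effects
F test) compares registrations and markers, with the degenerate
all-identical case defined as F = 0, p = 1. `fit_rigid_lsq()` computes
the least-squares rigid map used to extrapolate the full-head error
field (Kabsch/SVD, det = +1 enforced so reflections are impossible), and
`model_to_model_distance()` turns it into the per-vertex scalar field
exported for colour mapping.

Under pure isotropic probe noise the per-point error is chi-distributed
with 3 degrees of freedom, so its mean is `sigma * 2 * sqrt(2/pi)`; at
`sigma = 2.32` mm that is 3.70 mm, which the simulation reproduces within
2% over 10,000 probes. That sigma was chosen to place the simulated
output in the same magnitude band as published phantom measurements of
this registration approach (mean 3.7 mm); the simulation makes no claim
to reproduce hardware-specific error sources — headset tracking jitter,
display parallax, human depth perception — only the geometric and
statistical structure of the protocol.

## The synthetic phantom

`make_head_mesh()` builds a closed superellipsoid head (p-norm exponent
2.5, half-axes 75/95/115 mm in LPS axes) with a Gaussian-profile nasal
bump (22 mm default) providing the low-curvature-radius feature that
makes deployment well-posed; the seed drives a mild (2%) axis asymmetry.
LPS (x left, y posterior, z superior) was chosen to match the DICOM
patient frame implied by a CT reference image. `make_fixture()` assembles
mesh, six scalp fiducials with a 50 mm minimum separation, a seeded
scanner pose (origin near the head centroid, orientation jittered up to 6
degrees, emulating arbitrary gantry positioning), the marked reference
lines, the default scan geometry (FOV 251 x 251 mm, matrix 128 x 128,
slice thickness 0.625 mm — giving the familiar 1.96 x 1.96 x 0.625 mm
voxel), and a frame graph whose SLAM and image-target links are random
but whose extrinsic link is solved so the chain closes exactly. Every
generator is a pure function of (parameters, seed).

What the phantom does *not* emulate: real scalp deformation (skin shift,
head-clamp pressure), imaging distortion, marker wear, or any rendering
or perception effect. Tests passing on the phantom therefore validate the
geometry and the statistics of the method, not its clinical accuracy.

## Problem sizes and numerical choices

The default test head carries about 1,700 vertices / 3,500 faces, which
keeps a full deployment (projection of three planes per objective
evaluation, a few hundred evaluations) at a few seconds while holding the
contour chord error near 0.02 mm; the acceptance computations use 1,000
random chains for the transform algebra, 200 samples per circle for
intrinsic residuals, 500 per circle for extrinsic fits, and 10,002 probes
for the noise calibration. Tie-breaks at plane-vertex coincidences use a
1e-9 mm nudge; degenerate meshes (faces below 1e-9 mm^2), reflections,
collinear fiducial configurations, and planes that miss the surface are
rejected or flagged explicitly rather than patched over.

## Known limitations

The visibility model is a normal-direction test, not true occlusion, so
self-shadowing concavities (ears, nasal sidewalls on extreme poses) could
admit curve points a physical laser would not reach. The deployment
optimizer is local multi-start — it assumes an initial pose within a few
degrees and millimetres, as a human operator would provide. Freeze-state
drift is a translation-only random walk with placeholder magnitudes, as
no quantitative drift rate is available. And the simulated error budget
contains only geometry and probe noise; absolute accuracy numbers from
hardware experiments are reproducible here only in order of magnitude, by
choice of the noise sigma.
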