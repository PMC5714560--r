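---
title: "Methods: simulating and evaluating registration-based prostate contour propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating registration-based prostate contour propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During fractionated external-beam radiotherapy of the prostate, bladder and
rectal filling displace and deform the gland between treatment sessions.
When serial CTs are acquired during treatment, the planning contours can be
*propagated* onto each new scan by intensity-based image registration
instead of being redrawn by hand. Whether that is clinically acceptable
hinges on one comparison: is the propagation error small relative to how
much expert clinicians disagree with each other (interobserver variability)
and with themselves months later (intraobserver variability)?

`contourcast` implements that comparison as a fully synthetic, fully
testable pipeline. Because no patient data ship with the package, every
stage — CT volumes, deformations, observer contours — is simulated with a
known ground truth, and the evaluation machinery (ray casting, per-ray
t-tests, deviation summaries) is exactly the machinery one would run on
real DICOM data. Each stage reads and writes standard formats (NIfTI,
DICOM RT-STRUCT, a JSON contour interchange), so real data can replace any
simulated stage without code changes.

## Axis convention

One convention is used everywhere: **x** = patient right–left,
**z** = anterior–posterior, **y** = superior–inferior. The y axis is the
slice-stacking axis (5 mm spacing by default) and is deliberately the
*third* array axis; axial slice contours are (x, z) polygons at fixed y.
Elevation angles are measured from the +y (superior) pole. All coordinates
in user-facing objects are physical millimetres; voxel indices never leak
past the I/O layer.

## The phantom

`phantom_spec()` / `generate_phantom()` build a stylized pelvis: an
ellipsoidal prostate (semi-axes 23 × 19 × 21 mm, with an optional smooth
boundary perturbation so it is not a perfect ellipsoid), a spherical
bladder superior-anterior to it, and a posterior rectal tube carrying a
40 cm³ air balloon, inside a soft-tissue body cylinder. Default acquisition
geometry mirrors a helical single-slice scanner: 0.9766 mm in-plane pixels
(0.8301 mm for the second synthetic patient) and 5 mm slices. The default
grid is a reduced 160 × 160 × 36 prostate-centred field of view rather than
a full 512 × 512 pelvis; that choice keeps the full two-patient study at
desk scale (minutes, one CPU) and changes nothing methodological, since the
registration is restricted to the prostate-surrounding region anyway. A
full-resolution grid is one `phantom_spec(grid_shape = ...)` away.

Two intensity features matter and are both configurable: a smooth
band-limited texture (default 12 HU) that gives the similarity measure
something to lock onto inside otherwise flat tissue, and iid Gaussian noise
(default 4 HU). The anatomy is intentionally *not* realistic — no
beam-hardening, no HU calibration, no intra-fraction motion. What the
evaluation needs is contrast boundaries and an exactly known truth surface,
which is returned as a radial function r(elevation, azimuth): any surface
defined that way is star-shaped from its centre by construction, the
property the whole ray-casting parameterization presumes.

## Ground-truth deformation

`ground_truth_deformation()` composes a 12-parameter affine change
(translation, rotation, scaling, shear) with an elastic displacement field
on a coarse control grid (cubic B-spline, default 25 mm spacing). The
elastic part is not unstructured noise: its dominant term is a focal
Gaussian push (scale 0.8 × control spacing) centred near the posterior
prostate boundary and directed predominantly anteriorly — a surrogate for
rectal/bladder filling pressure, which is what actually deforms the gland
between fractions. A 25 mm/focal field is strongly non-affine across a
40 mm gland; a much smoother field would be nearly linear at prostate scale
and would make affine and elastic registration indistinguishable, which is
neither realistic nor informative. Mild random roughness is added on top;
the total dense displacement is scaled to stay below the configured
amplitude (default 4 mm), control displacements are clipped at 40% of the
control spacing (a sufficient condition against folding), and the composed
map's Jacobian determinant is verified positive numerically before use.
The deformed volume is produced by pull-back resampling, and the exact
dense map is returned for later recovery scoring.

## The observer model

`observer_model()` / `simulate_observer_contours()` emulate five clinicians
contouring slice by slice. Perturbations are applied **in-plane** (radially
within each axial slice), because that is where a contouring error can
live. Three components:

1. **Persistent systematic bias** per observer: a random low-order
   spherical-harmonic-like function of (elevation, azimuth) with RMS
   amplitude `bias_sigma_mm` (default 1.2 mm). It persists across images —
   the same clinicians contour the whole CT series, and an observer who
   over-segments the base does so on every scan. This matters: it makes
   each observer's propagated planning contour commensurate with their own
   follow-up contour, exactly as in the real study design.
2. **Independent per-point noise** with sigma
   `point_noise_sigma_mm × (1 + apex_base_inflation · |cos(elevation)|)`
   (defaults 0.8 mm and 1.5): inflated toward the superior/inferior poles,
   where 5 mm slices make the boundary genuinely ambiguous.
3. **Terminal-slice selection**: each observer includes an axial slice only
   if it falls inside their *perceived* apex/base extent (true pole radius
   + bias + pole-level noise), occasionally adding a small extrapolated cap
   contour one slice beyond the true extent. With 5 mm slices this
   quantized inclusion decision is the dominant superior–inferior
   disagreement mechanism, and it is what produces the characteristic
   pattern of large variability at the gland poles.

A repeat (long-term re-contouring) pass adds an extra per-observer smooth
drift (`repeat_drift_sigma_mm`, default 1.0 mm) with fresh noise, feeding
the intraobserver arm.

Calibration is closed-form and tested: pooled over the sphere, the expected
per-ray variance of in-plane radial deviations is
`bias² + noise² · (1 + k + k²/3)` for inflation coefficient k; a 3D radial
deviation measured along a ray at elevation θ is the in-plane deviation
times sin θ. Defaults were chosen once so the simulated interobserver row
lands in the low-millimetre regime typical of expert prostate contouring
(mean ≈ 1–1.5 mm, superior–inferior dominant); this is emulation of
plausible observer behaviour, not a fit to any dataset.

## Surface sampling: CMP, tessellation, 2048 rays

The prostate centre of mass (CMP) is the arithmetic mean of *all* contour
points pooled over the five observers of one image, and is the shared
origin for every surface measurement on that image — including the
propagated populations, which reuse the manual CMP of the same image so
that p-values reflect surface disagreement, not origin shifts.

`tessellate()` turns slice contours into a closed triangle mesh: each
polygon is resampled to 64 points by arc length (counter-clockwise,
starting near azimuth 0), consecutive rings are stitched with the cyclic
correspondence of minimal twist, and apex/base are closed with flat
centroid fans. Closedness (every edge shared by exactly two consistently
oriented triangles) is asserted in tests, and mesh area/volume have
analytic oracles (prism, sliced sphere).

`make_ray_fan()` casts 2048 rays: 32 elevation steps at the midpoints of
equal bins of (0°, 180°) — midpoints honour the strict bounds, so the poles
themselves are excluded — times 64 azimuth steps from 0°. Ray–mesh
intersection is an exhaustive Möller–Trumbore scan over all triangles,
reduced to the first positive hit; rays crossing more than once (possible
only for non-star-shaped inputs) are flagged and counted, and tests verify
the flag never fires on star-shaped fixtures. An independent oracle
(plane intersection + barycentric sign tests, vectorized the other way
around) reproduces the distances to 10⁻⁹.

Per ray, the five distances give the mean (the average segmentation
surface in radial form), the signed deviations, their sample standard
deviation (n−1 denominator: the five experts are a sample of a population
of experts), and absolute (x, z, y) deviation components obtained by
projecting the signed radial deviation onto the ray direction. Absolute
values are reported because symmetric noise would otherwise average to
zero per axis. Pooling over rays, observers and images yields the
12-column summary (X/Z/Y/3D × mean/std/max) used throughout.

## Registration

The registration module is a generic hierarchical intensity-based
affine + elastic method written for this package (the original clinical
tool it stands in for is not publicly specified). Design choices:

* **Similarity**: Pearson intensity cross-correlation (NCC) — appropriate
  for same-modality CT-to-CT. Out-of-volume samples are excluded from the
  correlation rather than zero-filled, avoiding border bias. Similarity is
  sampled in physical mm on the anisotropic grid (no resampling to
  isotropic), so the 5 mm axis contributes proportionally.
* **ROI restriction**: the planning prostate bounding box dilated by 20 mm,
  clipped to the reference volume. The box is held fixed on the reference
  rather than re-transferred each level: at the deformation magnitudes
  simulated here (≤ ~10 mm) the 20 mm margin absorbs the transfer entirely.
* **Affine stage**: 3-level Gaussian pyramid (factor 2; axes with few
  slices are not decimated), Nelder-Mead on normalized parameters
  (mm, degrees, percent scale/shear), optimized in three nested stages
  (translation; + rotation/scale; + shear) and cycled until the similarity
  stops improving — plain Nelder-Mead stalls short of the optimum on
  12 parameters without restarts. Transform direction is
  reference → floating (resampling convention); the centre of rotation is
  the ROI centre.
* **Elastic stage**: cubic B-spline displacement field on a control grid
  over the ROI, coarse-to-fine (20 mm then 10 mm, paired with pyramid
  levels), refining the affine map additively: T(x) = A x + b + u(x).
  The objective is NCC minus a bending-energy penalty on the control
  lattice (squared second differences; weight 0.005), maximized by
  L-BFGS-B with the analytic gradient (chain rule through trilinear
  interpolation of precomputed floating-image gradient volumes, projected
  onto the lattice by the separable B-spline adjoint). If the final map
  folds (non-positive Jacobian on the ROI) the penalty is increased
  ten-fold and the fit re-run once; a persistent fold is an error.
* **Determinism**: no stochastic sampling is used; fixed configuration
  gives bit-identical transforms.

Contour propagation maps planning contour points through the *inverse* of
the estimated map (analytic for affine, pointwise fixed-point iteration
`x ← A⁻¹(y − u(x))` for elastic, which converges for these bounded smooth
fields). When the mapped slices stay planar and no target grid is
requested, polygons are point-mapped directly (so an identity transform
returns the input exactly); otherwise the propagated surface is rebuilt by
tessellation and re-sliced onto the reference slice grid by casting
in-plane rays from the mapped centroid — for the star-shaped slices this
parameterization presumes, that is the plane–mesh intersection expressed
radially. Slices landing exactly on a cap plane are cast just inside the
mesh so terminal slices are retained. Points leaving the elastic field's
support are extrapolated with the affine part alone, with a warning.

## Evaluation statistics

Along each of the 2048 rays, the five manual distances and five propagated
distances are compared with a two-sample, two-tailed, pooled-variance
Student's t-test (df = 8); Welch's form is available as an option. The
pooled form is the conventional reading of a "two-tailed Student's t-test"
on two populations of five points each. p < 0.05 flags propagation failure
on that ray; the pass fraction is the share of rays with p ≥ 0.05. No
multiple-testing correction is applied — the per-ray maps are descriptive —
and the expected count of false flags under the null (0.05 × 2048 ≈ 102)
is recorded with every evaluation object.

Degenerate rays (both populations constant, which happens in noise-free
simulations) are decided at a geometric resolution floor: the constants are
called equal, p = 1, when they agree within 0.1 mm — below CT pixel size
and far below contouring precision — else p = 0 with a flag.

The intraobserver arm compares, per ray, the spread over observers of
(second pass − first pass) on one image with the spread of
(propagated − first pass); the binary map marks rays where the
intraobserver spread is smaller, and a two-sided variance-ratio (F)
p-value is reported alongside as a descriptive aid. In the pipeline the
repeat pass is simulated on the follow-up images so both spreads share one
ray fan.

## The experiment pipeline

`run_experiment()` mirrors the serial-CT study design: two synthetic
patients (the second with 0.8301 mm pixels), one planning CT plus three
follow-up CTs each, five observers on every image, a repeat pass for the
intraobserver arm, affine and elastic propagation of each observer's
planning contour, and per-fraction evaluation pooled into the three-row
(manual / affine / elastic) deviation summary plus box-plot statistics.
Per-fraction ground-truth deformations draw translations (sd 2 mm),
rotations (sd 1.5°) and scales (sd 1.5%) from named substreams of the
master seed, plus the 4 mm focal elastic change. All randomness flows from
one master seed through named substreams (`substream_seed()`), so any
stage can be re-run in isolation bit-identically; the manifest records the
config, seed and package version.

Observers contour on the *image's own slice grid* (`axis_coords(vol, 3)`),
not on a structure-centred grid — clinicians draw on the acquisition's
slices, and the relative phase between the slice grid and the gland is part
of what the method must cope with.

## What the tests show — and what they cannot

The test suite (and the acceptance script) establish: structural constants
(exactly 2048 unit rays at constant angular steps; 5-vs-5 populations per
ray); geometric correctness against analytic and brute-force oracles;
statistical calibration (type-I error 0.05 ± 0.01 under the null; p-values
to 10⁻⁹ against the t CDF); recovery of known affine and elastic truths
(translation within half an in-plane voxel, elastic mean surface error
under 1.5 mm and strictly below affine); a degenerate end-to-end identity
(zero noise + zero deformation → pass fraction 1, deviations < 0.1 mm);
and the ordering that elastic propagation error never exceeds affine error
across seeded replicate experiments — the qualitative conclusion that
elastic outperforms affine adjustment.

They cannot show performance on real pelvic CT: real images have low soft
tissue contrast, artifacts, and observer behaviour richer than any
three-component noise model. The synthetic interobserver magnitudes are
*emulation* of the published regime, not reproduction of any patient
dataset — patient-specific numbers from the clinical literature are not
reproducible without the underlying scans. Problem sizes were chosen once
for desk-scale runtime: the shipped test suite runs the study at a
80 × 80 × 28 grid (1.8 mm pixels) with one patient and fraction per
replicate, and the acceptance script runs the full two-patient,
three-fraction schedule at the default 160 × 160 × 36 grid.

## Numerical details worth knowing

* Tessellation resamples polygons by arc length; the prism and
  sliced-sphere oracles bound its discretization error (< 1% area, < 5%
  volume at 5 mm slices with midpoint-of-bin slice placement).
* Rays grazing shared mesh edges register in several adjacent triangles at
  one distance; crossing counts are de-duplicated by distance before the
  multiple-hit flag is raised.
* The interior test for a fan origin casts a parity ray in an
  irrational-ish direction to avoid the mesh's own seams.
* B-spline control lattices are padded by one spacing before the domain
  and two after, so every evaluation point has full cubic support; the
  dense field is componentwise bounded by the control displacements
  (non-negative weights summing to one).
* Fixed-point field inversion stops at 10⁻⁴ mm; the round-trip error
  budget asserted in tests is 0.05 mm.
* `substream_seed()` keeps every derived seed below 2³¹.
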