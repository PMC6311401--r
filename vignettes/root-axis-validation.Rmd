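---
title: "Validating predicted tooth root axes against CBCT-derived surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating predicted tooth root axes against CBCT-derived surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Digital dental models scanned from plaster casts show only tooth crowns;
some orthodontic software additionally *predicts* the roots from crown
landmarks. How accurate is such a prediction? The clinically meaningful
scalar is root **inclination**: the angle between the predicted root's long
axis and the actual root's long axis as segmented from cone-beam CT
(CBCT). `rootaxis` implements this measurement chain end to end and — since
clinical datasets of paired casts and CBCT scans are not freely available —
ships a synthetic phantom generator with known ground truth, so every stage
can be validated quantitatively.

The measurement pipeline is:

1. **Meshes in.** Predicted tooth models (crown + predicted root) in the
   scanner frame; CBCT-derived tooth surfaces (thresholded, here emulated by
   voxelization + isosurface extraction) in the CBCT frame; all STL.
2. **Registration.** The frames are aligned on the *crowns only* — the only
   anatomy both modalities see truthfully — by a landmark (Kabsch)
   initialization emulating manual alignment, refined with trimmed
   point-to-point ICP.
3. **Two axis estimators.** The predicted root's axis is the orthogonal
   (total-least-squares) line through ~50 points placed uniformly over the
   root surface, apex excluded. The CBCT root's axis is fitted through 4–5
   equidistant landmarks on each cross-sectional outline cut perpendicular
   to the root's long axis at 0%, 20%, 40%, 60% and 80% of the
   cervix-to-apex distance.
4. **Axes angle (AA).** `arccos(|d1·d2|)`, in `[0°, 90°]` — the inclination
   error, computed per tooth and summarized per tooth class with
   nonparametric statistics.

## Geometric estimators and their numerical choices

**Orthogonal line fit.** Anchor at the centroid; direction = first right
singular vector of the centered coordinates. If the two leading singular
values coincide within 1e-9 the direction is not identifiable; the fit then
warns and picks the lexicographically larger of the two equivalent
directions — reproducibility over fidelity for degenerate inputs.

**Preliminary axis.** Both estimators need a bootstrap axis to define slice
planes and the apical region. We use the principal direction of the root
vertex cloud, oriented cervix→apex by comparing the mean radial spread of
the two halves (the cervical half of a root is wider). Meshes whose first
two singular values are within a factor 1.5 are rejected as isotropic:
anatomical roots and their marching-cubes reconstructions show ratios of
1.9–3.1, spheres ~1.3, so the threshold separates the regimes cleanly. A
single pass suffices — plausible preliminary-axis errors move the slice
positions by under 2% of root length, below estimator noise.

**Point placement matters.** "Points placed uniformly" is ambiguous. We
measured three readings on synthetic roots (50 points each):

* independent area-uniform draws: ~5° mean axis error — area-uniform
  sampling concentrates points on the wide cervical third, and random
  azimuthal imbalance tilts the fit;
* area-stratified random draws: ~4° — the azimuthal imbalance remains;
* balanced rings (10 levels along the axis × 5 points equally spaced along
  the outline, seeded random phase per level): ~0.04° mean error.

Only the balanced reading is compatible with the known repeatability of the
clinical measurement (95% limits of agreement within ±4.5°, implying
per-measurement noise around 1.6°), and it is how operators and software
actually spread points. It is therefore the default
(`predicted_root_axis(..., method = "rings")`); the two random readings
remain available for noise studies. The seeded azimuthal phase keeps
re-measurement honest: a different seed gives different points, so
repeatability analyses exercise real sampling variation.

**Slicing robustness.** Mesh/plane sectioning chains triangle–plane
segments into closed outlines; vertices exactly on the plane are nudged by
1e-9 mm along the normal so every crossing triangle yields exactly two
intersections. Open chains are closed when the endpoint gap is below 0.5 mm
(non-watertight patches), else discarded with a warning. Boundary slices are
clamped 2% of root length inside the mesh: a plane through the extreme
vertex cuts the flat cervical cap obliquely whenever the preliminary axis is
slightly tilted and produces a partial-rim outline several millimetres
off-axis — a single such outline once tilted a canine's fitted axis by ~9°.
As a second guard, outlines whose centroid sits farther from the axis than
0.75 of their effective radius are rejected.

**Landmark start rule.** Equidistant outline landmarks start at the
outline's minimum-x vertex (ties: min y, then z). The rule is arbitrary but
deterministic; with 4–5 equidistant landmarks the fitted line is nearly
invariant to rotating the landmarks along the outline, so exact
rotation-equivariance is sacrificed for reproducibility (measured effect
under a 23° whole-scene rotation: under 0.1°).

## CBCT emulation

Real CBCT hands the workflow a thresholded isosurface at ~0.3 mm voxels.
The generator reproduces exactly that discretization chain — binary
voxelization of the watertight phantom (ray-parity test, 2-voxel margin)
followed by isosurface triangulation — and nothing else: no beam hardening,
scatter, or intensity noise, which the angle measurement never sees in this
design.

Triangulation is by **marching tetrahedra** (each cube split into six
tetrahedra sharing the main diagonal; consistent face diagonals make the
surface watertight). A binary mask carries no sub-voxel information, and
midpoint triangulation of binary data is known to overestimate curved
surface areas (we measured +8.5% on a sphere for classic marching cubes and
+27% for marching tetrahedra at 0.3 mm). A separable Gaussian pre-filter of
0.8 voxel (the `smooth_sigma` default of `extract_isosurface()`) restores
the partial-volume grading a real scanner produces; with it the
reconstructed sphere area is within ~0.7% of analytic and a straight
root's axis is recovered to ~0.2°. Curvature-induced offset of the 0.5
level set is `σ²·H` ≈ 0.02 voxel for these shapes — negligible.

## The phantom generator

The root is a tapered elliptical tube: cross-section radii scale as
`(1 − t)^taper` from cervix (`t = 0`) to apex (`t = 1`), with an optional
gradual bend over the apical third reaching `apical_curve_deg` at the apex;
the crown is a watertight cap sharing the cervical ring exactly. Shape
realism matters only insofar as slicing and sampling behave as on a real
root — the measurand is a direction, not morphology. Ground truth: the
best-fit line through the ring centers of the cervical 80% of the root,
deliberately the same anatomical region the CBCT estimator measures.

Defaults, chosen once from anatomical averages (mm; per class
upper/lower): root length 13/12.5 (centrals), 13/13.5 (laterals), 16.5/15.5
(canines); cervical semi-axes 1.8–3.8; apical curvature 3°/5°/10° for
centrals/laterals/canines — anterior roots are mostly straight with
curvature concentrated in canines, mirrored here in moderation so the
ground-truth axis stays well defined. Per-subject variation: ±8% root
length, ±10% radii, ±40% curvature, 2% per-ring radius wobble (leaving ring
centers on the centerline, so truth is unaffected).

The "software prediction" step is emulated by rotating the true root about
an axis through the cervix center perpendicular to the true axis: a
controllable injected angular error with uniform azimuth, plus 0.05 mm
vertex jitter. Injected errors are **half-normal** — an angle between two
axes is non-negative by construction, and observed AA distributions are
right-skewed for exactly that reason. Scales of 8.5°/11°/14.5° per class
give medians ≈ 8.1°/10.5°/13.8°, bracketing the clinically reported
per-tooth medians (7.7–13.9°) with canines worst. Frame misalignment
between scanner and CBCT coordinates: random rotation up to 8° and
translation up to 4 mm per arch (registration is per arch, since each arch
is scanned and segmented as a unit).

What the phantoms do *not* emulate: real crown morphology (registration
sees smooth parametric crowns, so real-data registration error is likely
somewhat larger), segmentation artifacts, metal artifacts, posterior teeth,
and any systematic bias of the actual prediction software — the generator
injects errors by construction, it does not model why a vendor algorithm
errs. Passing tests therefore validate the *measurement chain*, not the
vendor prediction.

## Registration

Kabsch initialization uses per-tooth cervix centers and incisal tips with
0.25 mm Gaussian placement noise, emulating manual alignment. Trimmed ICP
(default: 5000 seeded area-uniform source points fixed across iterations,
true point-to-triangle closest points via a uniform spatial grid, keep the
closest 90% of pairs, Kabsch update, stop at 1e-6 mm RMS change or 50
iterations) refines it. Trimming tolerates partial overlap — digital models
carry predicted roots the CBCT crowns lack. The kept-pair RMS is
non-increasing by construction (each step minimizes over correspondences,
then over transforms); the suite asserts it per iteration. On synthetic
arches, offsets within ±10°/±5 mm are recovered to well under 0.5° and
0.1 mm.

## Statistics

The battery mirrors standard practice for this design: Shapiro–Wilk
normality screen per tooth; Mann–Whitney sex comparison per tooth,
Bonferroni-adjusted across the 12 teeth; Kruskal–Wallis across Angle
classes; paired *t* and Bland–Altman (bias ± 1.96 SD of differences — the
classical multiplier, not the *t*-based variant) for repeatability. The
Mann–Whitney p-value is exact (permutation distribution) when the pooled
sample is ≤ 12 without ties, else normal approximation with tie and
continuity correction — the convention of mainstream statistical packages.
Two unstated conventions had to be fixed: quartiles use linear
interpolation between order statistics (R type 7, stated in the report),
and the age comparison uses a median split (no standard clinical age
grouping exists for this question). The paired sample-size relation
`n ≥ (s/d)² (t_{α/2,n−1} + t_{β,n−1})²` is solved by upward scan from the
normal-approximation start — the fixed-point iteration can two-cycle
because the ceiling interacts with decreasing t-quantiles; the scan is
exact because feasibility is monotone in n.

## Problem sizes and determinism

The validation suite runs the full replica at the study's own scale: 31
subjects × 12 anterior teeth (372 tooth pairs), 0.3 mm voxelization, vertex
jitter, random per-arch misalignments, mesh resolution 24 segments/ring.
At that scale the end-to-end regression of measured AA on injected error
yields a slope within a few percent of 1 and residual RMS ≈ 1°. Every
random stage (metadata, shapes, injected errors, misalignments, sampling
phases, ICP sampling) derives from a single master seed through a splitmix
scheme, so cohorts are reproducible bit-for-bit; the RNG state of the
caller is always restored.

## Known limitations

* Single-rooted anterior teeth only; no multi-rooted morphology.
* The angle is reported without direction (mesio-distal vs labio-lingual
  decomposition is out of scope by design).
* Registration quality on real crowns (cusps, wear facets, segmentation
  margins) is not represented by the smooth synthetic crowns.
* Tooth-level segmentation of a full-arch CBCT volume is assumed done
  upstream; the package consumes per-tooth surfaces.
* Statistics treat teeth as independent samples within a tooth position, as
  is conventional for this design; within-subject correlation across teeth
  is not modelled.
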