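---
title: "Measuring orbital-floor defect areas: slice-based vs surface-based"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring orbital-floor defect areas: slice-based vs surface-based}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

An orbital-floor blowout fracture leaves a defect in the thin bony plate
separating the orbit from the maxillary sinus. The defect's area drives
treatment: small defects are covered with a resorbable foil, large ones may
need a titanium mesh or a patient-specific implant. Clinically the area is
usually estimated from CT with a linear, slice-based protocol; a
surface-based 3D measurement on a segmented bone model is more laborious
but respects the fact that the floor is neither flat nor horizontal. This
package implements both measurements, a paired cohort comparison between
them, and a synthetic phantom generator with analytically known defect
areas so that each measurement can be validated against ground truth —
something patient data can never provide.

Throughout, x is mediolateral, y anteroposterior, z superoinferior, all
lengths in mm; coronal slices are constant-y planes and voxel `(i,j,k)`
(1-based) sits at `((i-1)dx, (j-1)dy, (k-1)dz)`.

## The slice-based 2D estimator

With `n` coronal slices showing the defect, slice thickness `d` and
per-slice mediolateral widths `l_i`, the clinical formula is

$$A_{2D} = n \cdot d \cdot \frac{\sum_i l_i}{n} = d \sum_i l_i ,$$

a Riemann sum of the defect's mediolateral extent along the
anteroposterior axis. `area_2d()` implements it exactly; `slice_widths()`
produces the widths either from the analytic rim of a phantom (each slice
plane intersected with the rim polygon — the idealized protocol) or from a
segmented bone mask (the run of bone-free columns interrupting the floor in
each coronal slice — the protocol as actually performed on images). The
width is a single straight-ruler extent per slice, not a sum of disjoint
segments, so multi-fragment slices over-count gaps exactly as a manual
ruler does. Two-examiner averaging is replaced by one deterministic
measurement with an optional seeded jitter (`jitter_sd`) to emulate
inter-rater noise.

The estimator's geometry is its weakness: the sum converges to the area of
the defect's *axial-plane footprint*, not of the defect itself. For a
floor tilted by $\theta$ about the mediolateral axis the footprint is the
intrinsic defect shrunk by $\cos\theta$, so

$$\frac{A_{2D}}{A_{true}} \to \cos\theta , \qquad
  \frac{A_{3D}}{A_{2D}} \to \frac{1}{\cos\theta} .$$

This is the mechanism behind the systematic 2D underestimate the package
quantifies; `analysis/04_tilt_law.R` sweeps it explicitly. On real images a
second, smaller effect compounds it: a tilted shell of thickness `t` sweeps
through `t·tan(θ)` of anteroposterior extent within a vertical column, so
near the rim its partial volume shades columns that the idealized protocol
would count as defect. The image-route 2D estimate therefore sits slightly
*below* `cos θ` times the truth (about 4–11 % extra at θ = 45–60° for
t = 1.2 mm), which strengthens, not weakens, the underestimation finding.

## The surface-based 3D measurement

`area_3d()` composes the full surface pipeline:

1. **Thresholding** (`threshold_bone()`): bone is `HU >= hu_min`, default
   300 HU — cortical bone sits far above soft tissue, and with the phantom
   defaults (bone 1200, tissue 40, noise SD 25) the margin is > 6 SD on
   either side, so the exact threshold is uncritical within a wide band.
2. **Virtual tissue dissection** (`largest_component()`): only the largest
   connected component is kept; 26-connectivity by default so thin oblique
   shells survive coarse spacing.
3. **Surface extraction** (`extract_surface()`): an isosurface of the
   binary field at level 0.5. Each grid cell is decomposed into six
   tetrahedra around a fixed diagonal; crossing tetrahedra contribute their
   edge-midpoint triangles. Because the decomposition is identical on both
   sides of every shared cell face, the surface of a solid blob is
   watertight by construction — no case table is needed, at the price of
   somewhat more triangles than a classic cube-table marching scheme. The
   grid is padded by one empty voxel so border-touching bone still closes.
4. **Rim detection** (`detect_rim()`): an automated stand-in for manually
   circling the defect. Superior-surface vertices (area-weighted vertex
   normal pointing upward; the smoothing matters, since per-face normals of
   a discretized tilted plane scatter widely) near the hint are projected
   onto their principal plane; per azimuthal bin about the aperture centre,
   the innermost edge cluster (min-ρ plus a 0.3 mm window) is averaged
   into one rim point, and two passes re-centre the aperture. An intact
   shell has superior surface arbitrarily close to any centre, which is
   exactly how "no rim" is recognized.
5. **Patch fit** (`fit_patch()`): a local frame from a PCA of the rim
   (w = smallest-variance direction, superior-facing; v = w × u), then
   least squares for $w = \sum_{i+j\le deg} c_{ij} u^i v^j$. Degree 2 by
   default: it captures the floor's concavity without chasing rim noise.
   The fit includes a support band of superior-surface vertices within
   3 mm outside the rim, playing the role of the surrounding surface a
   human operator selects. An exactly planar (or conic) rim with no
   support makes the quadratic design rank-deficient; the degree is then
   reduced automatically, so a coplanar rim always returns its plane with
   zero residual.
6. **Area integration** (`patch_area()`):
   $$A_{3D} = \iint_\Omega \sqrt{1 + w_u^2 + w_v^2}\; du\, dv$$
   over the rim's projection Ω, by Delaunay triangulation of the rim
   polygon plus an interior Steiner grid (0.25 mm default), lifting all
   vertices onto the polynomial and summing lifted-triangle areas. For a
   planar patch every lifted triangle lies in the plane, so the result is
   the projected polygon area exactly.

### The mid-surface convention

The rim is detected on the *superior* face of the shell, but the analytic
area of a shell defect is naturally defined on its mid-surface. For a
spherical bowl of radius R and thickness t the superior-face aperture is
smaller than the mid-surface defect by a factor $(1 - t/2R)^2$ — about 6 %
for t = 1.2 mm and R = 20 mm, far from negligible. `area_3d()` therefore
estimates the local shell thickness from the mesh (median distance from
superior band vertices to the nearest inferior-surface vertex) and offsets
rim and support points inward by t/2 along the normals of a preliminary
patch fit. For a planar floor this offset is a rigid translation and
changes nothing; for curved floors it removes the face-vs-mid-surface
bias. Set `mid_surface = FALSE` in `measure3d_config()` to measure the
superior face as-is.

### What accuracy to expect

On noiseless or realistically noisy phantoms at the default spacing
(0.4 / 0.75 / 0.4 mm), flat and moderately tilted defects measure within
about 2 % of truth, spherical caps within about 4 %, and the median
absolute error over a mixed 177-case cohort is about 1 %. One caveat is
worth knowing: a quadratic fitted to rim-plus-outside-band data
extrapolates the sphere's quartic sag term into the defect centre, so the
fitted *height field* can deviate from the true surface by ~0.2–0.4 mm
there (growing with band width) even though the *area* — which feels only
the gradient — stays within a couple of percent. Tightening the band
tightens the height tracking at some cost in orientation stability under
noise; 3 mm is a deliberate compromise.

## The phantom generator

`phantom_spec()` / `rasterize_phantom()` emulate the study's imaging
inputs: a thin bone shell (default 1.2 mm, a typical orbital-floor
thickness) in soft tissue (40 HU) above air (−1000 HU), voxelized at
0.4 / 0.75 / 0.4 mm so the coronal slice thickness matches the 0.75 mm
reformations the clinical protocol uses, with optional seeded Gaussian
noise (25 HU in cohort runs — ordinary soft-tissue CT noise; 0 where tests
need exactness). Three floor geometries are modelled, each with a
closed-form defect area:

| floor | defect | true area |
|---|---|---|
| flat plane | ellipse, semi-axes a, b | πab |
| plane tilted θ about x | ellipse (intrinsic) | πab (projection πab·cosθ) |
| spherical bowl, radius R | cap of base radius a | 2πRh, h = R − √(R²−a²) |

`sample_cohort()` draws mixed cohorts: 15 % flat, 45 % tilted (5–45°),
40 % spherical bowls (R 15–30 mm), semi-axes 5–14 mm (caps 5–12 mm,
capped at 0.9R) — chosen so analytic areas span roughly the tens-to-
650 mm² range reported for surgical cohorts. The paper gives no
distribution of fracture geometries; these ranges are a modelling choice,
fixed once, and all cohort-level numbers in this package are conditional
on them. What the phantoms deliberately do *not* model: herniating soft
tissue, trap-door fragments, comminution, neighbouring bone structures,
beam hardening. Passing tests show the measurements are correct on clean
shells of known geometry; they do not certify accuracy on clinically
messy anatomy.

## The paired comparison

`paired_test()` defaults to the Wilcoxon signed-rank test — the standard
paired analog of the Mann–Whitney U test (the literature on this study
design sometimes says "paired Mann–Whitney U", which names an unpaired
test; the paired intent is what matters, and an unpaired Mann–Whitney U
remains available behind `method = "mann_whitney_u"`). Exact p-values come
from the generating-function convolution of the (midranked) absolute
ranks, equivalent to enumerating all 2^n sign assignments, used up to
n = 25; beyond that a tie-corrected normal approximation with continuity
correction takes over. Sample SD uses the n−1 denominator; p-values are
two-sided. `fold_stats()` reports the mean of per-case 3D/2D ratios and
the ratio of means separately — they differ, and conflating them is a
classic error. `cohort_report()` emits the summary table (mean, median,
SD, min, max per method plus fold) and one line segment per case for a
paired-lines figure.

## Numerical choices, in one place

- Bone threshold 300 HU (configurable); connectivity 26.
- Isosurface at level 0.5 on the binary mask, one-voxel zero padding.
- Rim: 72 azimuthal bins, 0.3 mm edge-cluster window, two centring
  passes, minimum credible aperture radius 2 mm, superior = vertex normal
  z-component > 0.25.
- Patch: degree 2 (1–4 allowed, automatic reduction when rank-deficient),
  3 mm support band, PCA frame with superior-facing w and lexicographic
  sign tie-break.
- Integration: 0.25 mm Steiner grid with a sub-micrometre quasirandom
  offset (a perfectly regular grid is maximally cocircular, which Delaunay
  codes resent); triangles kept by centroid-in-polygon; two jittered
  retries if the triangulation still degenerates.
- Ties in comparisons at 1e-9 mm²; rim ordering by angle with index
  tie-break; floating subtraction of paired areas is exact only when the
  inputs are, which the test suite arranges via dyadic values where
  exactness is asserted.

## Problem sizes

The bundled analysis (`analysis/01` … `04`) and the acceptance script use
a 177-case cohort to mirror the study's n; it completes in roughly three
minutes on one core (about 0.9 s per case). The test suite exercises the
same paths on cohorts of 6–50 plus the 177-case directional check. Volumes
are sized automatically around each floor plate (typically 0.3–1.5 M
voxels), so nothing scales with an arbitrary bounding box.

## Known limitations

- The rim detector assumes one aperture near the hint, roughly star-shaped
  about its centre in the floor plane; multiple fragments or highly
  non-convex defects would need manual marking (the `defect_boundary()`
  constructor accepts any ordered loop, so external marking tools can be
  plugged in via STL + CSV).
- Widths are straight mediolateral chords; an examiner measuring the
  oblique in-plane trace of a steeply tilted floor would read slightly
  larger values. Which convention human raters actually used is not
  derivable from protocol descriptions; the chord is implemented and the
  alternative documented.
- Tilt beyond ~70° defeats the superior/wall classification (the superior
  face itself becomes nearly vertical); the generator's validation range
  stops at 80° and cohorts stay at or below 45°.
- The fold ratios reported for synthetic cohorts depend on the geometry
  distribution and are deliberately not tuned to reproduce any particular
  clinical cohort's fold.
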