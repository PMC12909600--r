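---
title: "Lattice SBRT planning geometry and plan evaluation with latticert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice SBRT planning geometry and plan evaluation with latticert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

Spatially fractionated (lattice) radiotherapy treats large, bulky tumors by
delivering a very high dose to a sparse array of small spherical sub-volumes
inside the tumor while holding the rest of the tumor at a much lower,
uniform dose. A same-day adaptive workflow makes this practical for urgent,
symptomatic presentations: the target is contoured, the sphere lattice is
generated and cropped to the tumor, a plan is optimized and checked against
a fixed objective template, and an independent dose recomputation verifies
it — all in one session.

`latticert` implements the computational core of such a workflow on
voxelized anatomy so that every stage can be exercised, tested and measured
with no external data: lattice generation and cropping, margin-based
structure derivation, a stand-in dose painter, DVH objective evaluation,
contour-similarity verification, and 3D gamma comparison, plus a seeded
synthetic-patient generator that supplies the anatomy.

## Regimen and planning structures

The modeled course has two phases, totalling 20 Gy at the tumor level:

* **Phase 1** (single fraction): 12 Gy to `PTV_High`, the kept sphere
  lattice, and 4 Gy to the tumor-level target, with hotspots capped at
  15 Gy (125% of the sphere dose).
* **Phase 2**: four fractions of 4 Gy to `PTV_Low`.

Structures are derived from the physician GTV and the body contour:

| Structure | Derivation | Objectives |
|---|---|---|
| `_SpheresMatrix` | uniform 3D lattice of 10 mm spheres, 20 mm center-to-center | none |
| `PTV_High` | spheres surviving a 1 cm GTV retraction | V12Gy ≥ 90%, D0.03cc ≤ 15 Gy |
| `PTV_Low` | GTV + 5 mm (clinically 3–5 mm), clipped to Body | D95% ≥ 4 Gy, D0.03cc ≤ 12 Gy, Dmean 3.5–5.5 Gy |
| `Ring` | (PTV_Low + 3 cm) − PTV_Low, clipped to Body | D0.03cc ≤ 4 Gy |

`sfrt_objectives()` encodes this template; `sfrt_objectives(strict = TRUE)`
swaps in the clinical-acceptance variant (`V4Gy ≥ 95%`, Dmean ≤ 5.0 Gy),
which is what the pipeline gates on.

## Grid model and numerical conventions

All masks and doses live on one axis-aligned regular grid with a
voxel-center convention: voxel `(i,j,k)` (0-based) has world center
`origin + (i,j,k) * spacing` in mm. A voxel belongs to an analytic solid
iff its *center* is inside (no partial-volume weighting); this makes every
geometric operation verifiable by exhaustive enumeration. Synthetic cases
use 2 mm isotropic spacing (CBCT-like and fast enough for desk-scale runs);
geometry unit tests use 1 mm. File I/O is NIfTI-1 with the geometry in the
transform; non-axis-aligned orientations are rejected rather than silently
resampled.

Conventions worth knowing:

* Dice of two empty masks is defined as 1 (identity convention).
* Mean surface distance is the symmetric average of the two directed mean
  nearest-surface distances between boundary voxel sets (occupied voxels
  with an unoccupied 6-neighbour).
* `D0.03cc` uses partial-voxel linear interpolation on the
  descending-sorted voxel doses (a 2 mm voxel is 0.008 cc, so roughly four
  voxels straddle the 0.03 cc cut); ties are broken by a stable descending
  sort.

## Lattice generation and cropping

The lattice is a simple-cubic grid of sphere centers with equal step on all
axes, symmetric about a center point (by default the GTV centroid),
covering the matrix extent inclusive of its boundary planes. The defaults —
10 mm spheres, 20 mm spacing, 200 mm extent — give 11 planes per axis, 1331
candidate spheres; the extent is chosen automatically as the smallest
default (200, then 300 mm) exceeding the GTV bounding box plus one spacing.
The underlying clinical tools only require a "3D grid" with user-set
minimum spacing, so the topology is kept behind one constructor where an
offset-plane variant could later be added.

Cropping retracts the GTV by 10 mm (exact Euclidean distance, see below)
and keeps a sphere only when at least 95% of its voxelized volume survives
the retraction. In the clinical workflow partially cropped spheres are
deleted by hand; the 95% completeness tolerance automates that review, and
is configurable because exact "fully inside" tests are brittle at 2 mm
voxelization. For a spherical GTV of radius `R` this reproduces the
analytic criterion `|c| ≤ R − retraction − r_sphere` to within one voxel,
which the test suite checks explicitly. Small or irregular tumors can lose
every sphere; that is a legitimate outcome (the case is then flagged, not
silently planned).

## Margins by exact Euclidean distance transform

Expansion and retraction are defined through the exact Euclidean distance
between voxel centers, computed with a separable exact squared distance
transform (compiled code, anisotropic spacing supported): a voxel is in the
expansion iff its distance to the nearest occupied center is ≤ the margin,
and in the retraction iff it is occupied and farther than the margin from
the nearest unoccupied center. This gives isotropic ("uniform") margins
even on anisotropic grids, unlike structuring-element dilation. The two
operations are duals through complementation, monotone in the margin, and
satisfy the closing property `retract(expand(A,m),m) ⊇ A`; all three are
exercised as property tests against an exhaustive all-pairs oracle on small
grids.

## The dose painter is a stand-in, by design

The clinical optimizer is a commercial black box, so plan *construction*
here is an openly simplified kernel painter whose only claim is that it
deterministically satisfies the objective template on well-formed
geometries — which is exactly what the evaluation stack needs to be
exercised end-to-end. It makes no beam-physics claims and no attempt at
realism in the penumbra shape.

* **Base bath**: `D_base(x) = D_gtv` inside `PTV_Low`, and
  `D_gtv · exp(−d(x)² / 2σ_p²)` outside, where `d(x)` is the Euclidean
  distance to `PTV_Low` and `σ_p = 4 mm`; outside the target the bath is
  additionally hard-capped at the 4 Gy ring objective.
* **Sphere boost**: each kept sphere contributes a flat plateau at exactly
  the 12 Gy sphere dose inside its radius with a Gaussian shoulder
  (`σ_b = 4 mm`) outside; multiple spheres combine by voxelwise maximum.
* **Combination**: inside the GTV the plan is `max(base, boost)`; outside
  the GTV only the base applies. Maximum (not sum) avoids double-counting
  that would breach the 15 Gy hotspot cap where a shoulder overlaps the
  bath.

The plateau sits at exactly the sphere prescription rather than above it:
any higher plateau would push the near-sphere GTV voxels (which see the
kernel shoulder) above the 12 Gy `PTV_Low` dose cap, while exactly 12 Gy
makes sphere coverage (`V12Gy = 100%`) and the `PTV_Low` near-maximum
(`D0.03cc = 12 Gy`) hold simultaneously by construction. Consequences worth
noting: Phase 1 plans here have a global maximum of 12 Gy, not the up-to-15
Gy heterogeneity a real optimizer produces, and `PTV_Low` coverage is
exact rather than approximate. Painting fails loudly — naming the violated
constraint — when a geometry cannot meet the caps (for example a sphere
whose voxels fall outside the GTV), rather than silently degrading
coverage.

Phase 2 is the base bath alone at 4 Gy per fraction; accumulation is plain
voxelwise addition on the common grid, so the course total in GTV tissue
away from the spheres is 4 + 4×4 = 20 Gy.

## Gamma comparison

`gamma_3d()` computes, for every reference voxel at or above the low-dose
threshold (10% of the reference maximum), the minimum over nearby evaluated
samples of `sqrt((Δr/DTA)² + (ΔD/(δ·D_max))²)` with global normalization to
the reference maximum (local normalization is a flag). The search pattern is
a displacement grid sorted by distance with step `min(eval spacing, DTA)/2`,
truncated at a radius of `3×DTA`, with trilinear interpolation of the
evaluated dose and early termination once the distance term alone exceeds
the running minimum. The radius cap bounds the worst reportable gamma at
about 3 for far-off disagreements, which does not affect the pass rate
(γ ≤ 1) it gates on. Both criteria presets in clinical use ship: 3%/2 mm
(plan acceptance) and 5%/3 mm (secondary-verification reporting), each with
the 10% threshold and a 90% pass-rate expectation; 5%/3 mm is the default
because that is the setting reported by secondary-check systems. In the
pipeline the "independent recomputation" is surrogated by a global 2%
rescale plus a 1 mm rigid shift of the painted dose — a perturbation chosen
to sit well inside 5%/3 mm, standing in for the systematic differences
between two dose engines.

## Synthetic cohort: what it emulates, and what it does not

`generate_cohort()` defaults to five thoracic and five extremity cases,
mirroring a typical retrospective SFRT cohort. Thorax bodies are elliptic
cylinders (~300 × 200 mm cross-section), extremities tapered circular
cylinders (radius 60 → 50 mm) whose narrowness forces the 3 cm ring to be
clipped by the body — deliberately exercising the body-clipping rule. GTVs
are ellipsoids or smooth lobed unions of 2–3 ellipsoids (soft-min blending
of their implicit functions), with per-axis extents drawn within the 40–120
mm band the workflow targets (extremity cross-axes capped near 80 mm to fit
the body); centers are jittered a few mm per case. Every mask is
deterministic given the case seed.

The re-contouring step of an adaptive session is surrogated by
`perturb_contour()`: a level-set shift of the GTV by a smooth Gaussian
random field normalised to a 1 mm RMS boundary displacement, then verified
with Dice and mean surface distance exactly as a re-drawn contour would be.

What passing tests on this cohort do **not** show: realism of CT/CBCT
appearance, inter-fraction deformation, OAR-sparing trade-offs (OARs are
placed but carry no objectives by default), or optimizer behaviour —
the painter satisfies objectives by construction, so cohort-level passes
validate the *geometry, evaluation and QA chain*, not plan optimality.

## Problem sizes and runtime choices

Synthetic thorax cases voxelize to about 2.1 M voxels (157×107×127 at
2 mm), extremities to about 0.7 M; one full Phase 1 pipeline run (lattice,
derivation, contour QC, painting, evaluation, gamma) takes on the order of
10 s on one CPU, and the default 10-case cohort about two minutes. Oracle
tests run on ≤ 32³ grids where exhaustive O(n²) comparisons are cheap.
These sizes were chosen as the package's own desk-scale defaults; grid
spacing, body dimensions and extents are all parameters.

## Known limitations

* The painter's penumbra is a Gaussian of boundary distance — adequate for
  exercising DVH/gamma machinery, not for predicting clinical falloff.
* Only axis-aligned grids; DICOM-RT import/export is out of scope.
* The lattice topology is simple-cubic; offset-plane arrangements used by
  some centers are not yet implemented.
* The PTV_Low Dmean window is 3.5–5.5 Gy in the planning template but
  3.5–5.0 Gy in the strict clinical variant; the pipeline gates on the
  stricter bound by default.
* Monitor units, beam models and deliverability are outside the package's
  scope entirely.
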