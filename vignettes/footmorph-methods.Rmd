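---
title: "Methods: template-to-scan foot morphing, FE preprocessing and regional pressure statistics"
author: "footmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-to-scan foot morphing, FE preprocessing and regional pressure statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footmorph)
```

## The problem

Subject-specific finite-element foot models normally require MRI or CT to
recover the internal bone geometry. A much cheaper route is to scan only the
outer foot surface, then *morph* a generic template foot — outer surface plus
a merged internal bone — onto the scan. footmorph implements that morphing
workflow, quantifies its geometric accuracy, assembles the resulting
geometry into a solver-ready finite-element input deck for balanced-standing
plantar pressure prediction, and provides the regional statistics used to
compare predicted and measured pressure maps. Solving the FE model is out of
scope: the package's contract ends at a valid input deck.

All geometry lives in a right-handed frame with +z superior, +y anterior
(toe direction), millimetres everywhere. Stresses and moduli are N/mm^2
(= MPa), forces are N, pressures are kPa.

## Registration model

Morphing is staged:

1. **Affine registration.** Sixteen named anatomical landmarks (posterior
   calcaneus through fifth toe tip; `FOOT_LANDMARKS_16`) are placed on both
   template and target. `fit_affine()` finds the 4x4 homogeneous matrix
   minimising the summed squared landmark misfit; with four non-degenerate
   pairs the fit is exact, with more it is least squares. Coplanar or
   collinear source landmarks are rejected as rank-deficient.

2. **RBFPT — landmark-based RBF.** A radial-basis-function interpolant
   `f_i(x) = sum_j c_ij Phi(|x - x_j|)` (one coefficient column per axis) is
   fitted from the affine-transformed template landmarks to the target
   landmarks and applied to the template surface and bone. Three kernels are
   supported: multiquadric `sqrt(r^2 + beta)` with shape parameter
   `beta = 0.2` (treated as a squared-mm offset on raw coordinates),
   thin-plate `r^2 log r`, and triharmonic `r^3`. A multiquadric printed with
   a minus sign under the root is available behind `legacy_sign = TRUE`; it
   is imaginary for `r < sqrt(beta)` and errors there, which is why the
   plus-sign form is the default.

3. **RBFST — surface-correspondence RBF.** `n` vertices of the RBFPT-scaled
   surface (default 1000) are sampled uniformly at random without
   replacement under a fixed seed, each paired with its closest point on the
   target surface (point-to-surface, since scanned meshes are not
   index-aligned with the template; an index-pairing and a farthest-point
   sampling option exist). A second RBF fitted on these pairs — plus the
   landmark pairs, so anatomical landmarks never drift — refines surface and
   bone.

`run_pipeline()` dispatches the four study variants: RBFPT alone, or
RBFPT+RBFST with the THI, MUL or TRI kernel.

### Numerical choices

Thin-plate (and triharmonic) kernels are only conditionally positive
definite, so the pure-RBF system is not guaranteed solvable. `fit_rbf()`
therefore augments the system with a full affine tail under the moment
side-conditions `sum_j c_j = 0`, `sum_j c_j x_j^T = 0` by default. Two
useful consequences: the bordered system is well posed, and any exactly
affine correspondence is absorbed entirely by the tail (RBF coefficient norm
numerically zero). A tail-free fit with a small Tikhonov ridge
(`lambda = 1e-10` times the mean absolute kernel value) is available.

On raw millimetre coordinates the triharmonic kernel produces matrix entries
of order 1e7 next to unit constraint rows, so the *reciprocal condition
number* of the bordered system looks catastrophic even though partial-pivot
LU solves it to ~1e-10 mm source residual. The solver therefore gates on the
*achieved interpolation residual* (must be below 1e-6 mm) rather than on
`rcond`, and reports the condition number only when that gate fails.

Closest-point queries brute-force all triangles in compiled code; ties
resolve to the lowest triangle index for determinism. Sampled RBFST vertices
that coincide with a landmark source within 1e-3 mm are dropped to keep the
interpolation system nonsingular (landmarks ride on mesh vertices, so a
sampled vertex can be a landmark).

## Geometric error model

`error_map()` evaluates, at every vertex of the scaled surface, the signed
Euclidean distance to the closest point on the target surface. The magnitude
is exact (verified in the tests against a pure-R all-triangles oracle); the
sign comes from the angle-weighted pseudo-normal at the closest feature
(face, edge or vertex), which is the standard way to orient distances to an
*open* surface — the scan is trimmed, so watertight containment is
unavailable. Negative means inside the target.

`error_stats()` reports means over the strictly positive and strictly
negative values separately (zeros belong to neither), plus the extreme
values — the positive/negative averaged and maximum distances conventionally
reported for surface-scaling accuracy. Means are vertex-weighted, not
area-weighted.

## Constitutive models

Three materials ship with the deck writer, with the balanced-standing foot
model defaults:

* merged bone: linear elastic, E = 10000 MPa, nu = 0.34;
* encapsulated bulk soft tissue: second-order polynomial hyperelastic,
  `U = sum_{i+j=1..2} C_ij (I1bar-3)^i (I2bar-3)^j + sum_i (1/D_i)(J-1)^{2i}`
  with C10 = 0.8556, C01 = -0.0584, C20 = 0.03900, C11 = -0.02319,
  C02 = 0.00851 N/mm^2, D1 = 3.65273 mm^2/N and D2 = 0 — a zero `D_i` means
  the corresponding volumetric term is *absent*, the usual solver
  convention, never a division by zero;
* skin: first-order Ogden in the printed normalisation
  `U = (2 mu / alpha^2)(l1^a + l2^a + l3^a - 3)` with mu = 0.122 MPa,
  alpha = 18, treated as incompressible (no volumetric coefficient is given
  for skin, and membranes are commonly modelled incompressible). This
  normalisation coincides with the Ogden card convention of the target
  solver dialect, so `mu` maps through the deck unchanged with D = 0.

Deviatoric invariants follow `J = l1 l2 l3`, `lbar_i = J^{-1/3} l_i`,
`I1bar = sum lbar_i^2`, `I2bar = sum lbar_i^{-2}`; pure dilation leaves both
at 3. `uniaxial_nominal_stress()` differentiates the energy analytically
under the incompressible uniaxial substitution `l2 = l3 = l^{-1/2}` and is
verified against central finite differences of the energy to 1e-6 relative
over stretches 0.7–1.5.

## FE model assembly

`build_model_spec()` assembles the four parts — merged bone (C3D4 tets),
bulk soft tissue (C3D4), a 2-mm M3D3 membrane skin generated by
`make_skin_layer()` over the bulk surface (sharing its nodes, thickness as a
section property), and a C3D8 ground plate — with foot–plate friction 0.6, a
vertical plate load of half the body weight, an Achilles force of a quarter
of the body weight, the plate fixed in all but the vertical direction, and
the proximal tibia/fibula/skin sections fully fixed. Target element sizes
are 3 mm (bone) and 5 mm (soft tissue, plate); `convergence_ladder()` emits
the halving refinement sweep (20 to 1.25 mm) with the usual "< 5% peak
pressure deviation" acceptance rule recorded as metadata for the external
solver. Volume meshing itself is delegated to external meshers — the package
validates and carries `volume_mesh` objects but does not tetrahedralise;
`make_block_volume()` provides structured blocks for plates and tests.

The node sets the study leaves unspecified (Achilles attachment, proximal
constraint sections, plate load set) are user-suppliable; when omitted they
are derived geometrically (posterior-superior bone nodes, top-5% bands, all
plate nodes) with a notice. `write_inp()` is byte-deterministic and
`read_inp_summary()` recovers the inventory, skipping unknown keywords with
a warning.

## Regional pressure statistics

Plantar pressure maps are uniform grids of kPa values. The foot axis runs
from the pressure-weighted centroid of the posterior 15% band through the
anterior band centroid (overridable), and `side` fixes which side of the
axis is medial. The study names seven barefoot regions (medial/lateral heel,
midfoot, medial/middle/lateral forefoot, hallux) and eight orthosis regions
(midfoot split medially/laterally) but not their borders, so the borders are
this package's convention and are configurable: longitudinal cuts at
0.30/0.60/0.85 of footprint length, heel (and midfoot in the eight-region
scheme) split at the axis line, forefoot columns at 0.40/0.70 of
medial-to-lateral width, hallux the medial third of the toe band with the
remaining toe cells joining the adjacent forefoot columns so every loaded
cell is covered. Masks are disjoint by construction and coverage is checked
on every call.

`region_peaks()` extracts per-region maxima (empty regions report 0 with a
warning). `compare_paired()` applies the Shapiro-Wilk test at alpha = 0.05
to the paired *differences* — the study's gate could equally be read as
testing each sample; testing the differences is what the subsequent paired
tests assume, and the choice is overridable via `test =` — then runs a
paired t test if normality is not rejected and the Wilcoxon matched-pairs
signed-rank test otherwise (exact p for n <= 25 without ties, normal
approximation with continuity correction above; all-zero differences give
the degenerate p = 1). `agreement()` reports Pearson's r and the
Bland-Altman offset with 95% limits of agreement
(`offset +/- 1.96 sd(differences)`). All tests are two-sided.

## The synthetic benchmark

No scans or templates can be redistributed (the study's template is
proprietary and its scans are human-subject data), so `make_template()`
generates a parametric stand-in: a closed foot-like surface (tapered
half-ellipsoid heel, flattened sole, widened forefoot wedge, toe bulge) of
default length 250 mm — an adult foot — with a bone core scaled inward by
0.6 about the centroid, six seeded smooth Gaussian bumps (+-1.5 mm) breaking
the left-right symmetry, and the 16 canonical landmarks placed at fixed
parametric stations and snapped to the nearest mesh vertex (an error is
raised if the resolution cannot host 16 distinct landmark vertices). The
default resolution (48 rings x 36 vertices, 1730 vertices / 3456 faces)
keeps every benchmark below a minute on one CPU; the problem sizes used by
the tests and the acceptance script are this fixture, 1000 RBFST samples and
50-point oracle batches.

`deformation_field()` supplies the ground truth: an affine map plus Gaussian
radial bumps `disp * exp(-r^2 / (2 radius^2))`, with bump magnitudes capped
at `radius/2` so the field stays smoothly invertible (the displacement
gradient stays well below 1). `benchmark_field()` fixes the standard
conditions — 6/10/−4% anisotropic scaling, 3-degree rotation, a few mm of
translation, and one 5-mm bump of 40-mm radius at the medial arch — chosen
once as a realistic inter-subject difference plus a local arch deformation.
On this benchmark the RBFPT+RBFST/THI pipeline with 1000 samples recovers
the target to a mean absolute signed distance below 0.5% of the fixture's
bounding-box diagonal, improves on RBFPT alone, and the mean error is
non-increasing over 100/500/1000 samples.

`make_pressure_map()` emulates a standing footprint as two Gaussian lobes
(heel-dominant by default, 121 vs 107 kPa) with seeded noise of at most 2%
of the larger peak; lobe centres snap to the grid so the stated peaks are
attained exactly.

**What passing these tests does and does not show.** The fixture is smooth,
closed, noise-free and exactly landmark-consistent; the ground-truth
deformation is low-frequency. Real scans bring landmark placement error,
scanner noise, open boundaries from trimming, and toe-region deformations
far rougher than one arch bump — the regime where real morphing error
concentrates. Passing the benchmark validates the *machinery*
(interpolation exactness, kernel algebra, error accounting, determinism),
not clinical accuracy on real feet.

## Known limitations

* Binary STL stores float32, so round-trips through it are only accurate to
  ~1.5e-5 mm at 250-mm coordinates; ASCII STL/PLY/OBJ round-trip to 1e-6 mm.
* The brute-force closest-point query is O(points x triangles); adequate up
  to a few thousand triangles per surface, not for raw scanner meshes —
  decimate first.
* Inside/outside classification relies on pseudo-normals and consistent face
  orientation; inconsistent winding flips signs.
* The deck writer emits a dialect subset (no steps beyond one static step,
  no contact pair wiring beyond the surface-interaction card); it is a
  preprocessing artefact, not a full solver interface.
* Region borders are conventions; comparisons across software should fix
  them explicitly.
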