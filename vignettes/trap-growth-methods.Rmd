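---
title: "Methods: growing-tissue models and morphometrics for Utricularia traps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growing-tissue models and morphometrics for Utricularia traps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the package's science is implemented: the growth
model and its assumptions, the parameters that matter and their defaults,
the synthetic-data generators and what a green test does and does not
establish, the numerical decisions, and the known limitations.

## The growing-canvas model

The tissue is treated as a continuous sheet of defined thickness (the
*canvas*), here a hollow sphere of diameter 100 µm with a 30 µm wall,
matching the trap at 4 days after initiation (DAI). Growth is *specified*
per region as a rate tensor — `K_par` along the local polarity, `K_per`
perpendicular to it in the plane, `K_nor` through the thickness — and the
*resultant* deformation over a time step `dt` is whatever shape minimises
the residual elastic strain energy between the actual deformation and the
specified stretch `exp(K dt)` in each element's local frame. After every
step the residual strain is dissipated completely: the deformed state
becomes the new stress-free reference, modelling irreversible (plastic)
wall yielding in plant growth. Shape change is therefore an emergent
property: no curvature is ever prescribed.

Two conflict modes drive curvature. *Areal conflict*: regions specified to
grow at different rates (isotropically) frustrate each other and the sheet
buckles — e.g. the midline-promoted (MID) sphere flattens into an oblate
spheroid, and a fast ventral arc bulges outward. *Directional conflict*:
uniform areal rates but spatially varying orientations of anisotropy — the
same oblate spheroid arises with growth now parallel to the midline, and a
ventral arc that extends without bulging. The integrated model combines
both, and reproduces the full shape series best.

### Discretisation

The canvas is an icosphere (subdivision level 4 by default, 5120 triangles,
deterministic construction) extruded into a single layer of 6-node wedge
elements between the inner and outer wall surfaces. Elements are assembled
in a local corotational frame (z along the mid-surface normal) with 3-point
in-plane x 2-point through-thickness quadrature; the transverse-shear rows
of the strain operator are evaluated at the in-plane centroid (selective
reduced integration). Without that reduction flat linear elements lock in
transverse shear — bending becomes independent of thickness — and the
buckling that resolves growth conflicts is suppressed. Uniform-strain
(membrane) response is unaffected, so the conflict-free oracles remain
exact.

Rigid-body motion is fixed by pinning six well-chosen degrees of freedom.
Because linearised rigid modes are exactly in the stiffness null space, the
constrained minimiser coincides with a global minimiser (the constraint
surface crosses every rigid-motion coset); afterwards the best-fit
linearised rigid motion is removed, so the gauge adds no artificial stress —
verified by the conflict-free growth tests, which recover specified growth
to machine precision.

The elastic constants are `E = 1` (arbitrary; shapes depend only on
growth-rate ratios) and Poisson ratio 0.3. Sensitivity runs with nu between
0 and 0.45 changed the reported resultant rates by a few percent only.

## Regional factors and the polariser

Factors are installed on the initial sphere and are material thereafter.
Graded factors decay exponentially with geodesic distance to their seed
region: `i = exp(-d/l)` with spread length scales MID 15 µm, STK 10 µm,
mouth 10 µm. This analytic profile was chosen over a numerical
diffusion-to-steady-state solve because it is the same exponential family
with the same length scale while being exactly mesh-resolution invariant
(a tested property), exactly mirror-symmetric, and strictly decreasing with
distance; a Dirichlet seed band one triangle wide cannot be, since its
physical width halves with every subdivision level.

**VEN spread (8 µm).** The integrated model widens the VEN domain by
thresholding: `i_ven > t_ven` with `t_ven = 0.01`. The widened domain's
extent therefore depends directly on the VEN spread. With a 15 µm spread
the thresholded domain covers ~40 % of the canvas, which contradicts the
published rendering of a broadened-but-band-like VEN domain and destroys
the integrated model's straight extended ventral midline — its central
qualitative prediction. With 8 µm the widened domain is ~16 % of the
surface and the published ordering of ventral-midline straightness
(integrated and directional straighter than areal) is reproduced. The 8 µm
default is a geometric consequence of the printed `t_ven`, not a fit to any
measured rate.

The polariser is the steady state of surface diffusion (cotangent
Laplacian, lumped mass) with production proportional to the stalk factor
and degradation enhanced at the mouth, then rescaled to [0, 1] and frozen
to the material; only its gradient direction is used, so the absolute
diffusivity (200 µm² h⁻¹), basal turnover (0.005 h⁻¹) and mouth turnover
(10 h⁻¹) affect only the smoothness of the field. The polarity is
re-derived from the frozen polariser on the deformed surface after every
step. Triangles whose gradient falls below 1e-6 of the field maximum are
flagged isotropic-only; in practice this only ever affects the exact
organiser poles.

The mouth centre sits 70 degrees from the stalk pole along the ventral
meridian (disc radius 15 degrees), and the stalk cap has a 15 degree
radius; the sphere's mirror plane is x-z, with the stalk pole at -z. The
mesh is built to be exactly mirror-symmetric (trigonometric zeros snapped),
and a property test verifies that symmetric inputs give mirror-symmetric
outputs; over long runs roundoff asymmetry grows slowly (~0.3 % of trap
size over 78 steps at level 3), which is why material (factor-based) rather
than spatial (plane-based) definitions are used for midline measurements.

## KRN parameters

All rate parameters are the published ones: areal models
`b_planar = 0.0145 h⁻¹, p_mid = 0.165, h_stk = 1.4, p_ven = 0.2`;
directional models `b_planar = 0.015, p_mid = 0.35, h_stk = 1.5,
p_ven = 0.5`; integrated adds `h_ven = 0.8, t_ven = 0.01`; everywhere
`b_thickness = 0.005 h⁻¹`, and the thickness-variant preset uses
`p_th = 0.5`. Factor levels are capped at 1 before evaluation so that
"at the midline" corresponds to `i = 1`. Note the printed constraint
"`K_per + K_par = 0.033 h⁻¹`" is approximate: `2 x 0.0145 x 1.165 =
0.033785`, and the equations are implemented as printed.

## Cells, divisions, clones

Cells tile the outer surface only (one layer), as a Lloyd-relaxed random
Voronoi tessellation of the sphere (convex-hull Delaunay, 40 sweeps),
bound to the mesh by barycentric coordinates so advection is implicit.
Division: a competent cell reaching `T_A = 70 µm²` is split by a wall
through its centroid perpendicular to its second-moment long axis, with a
seeded +-10 degree jitter; daughters inherit clone marks and competence.
Competence ends everywhere at 6.5 DAI and is absent where the stalk factor
exceeds 0.5. A cell is checked once per solver step and divides at most
once per step. The mean initial cell area honours the published 50 µm²
(the published "approximately 350 cells" is inconsistent with the sphere's
area at that mean; the cell count is configurable). Non-convex polygons
(possible after repeated divisions) are split by choosing the wall-chord
pair whose midpoint lies inside the polygon nearest the centroid; a failed
split retries without jitter and across a sweep of wall angles before
raising an error naming the cell.

Clone metrics follow the measured protocol: per connected marked patch,
the major/minor axis lengths from the patch's second-moment eigenvectors
(clone anisotropy), the number of distinct cells intersected by each axis
(cell-number anisotropy), and their quotient (cell-shape anisotropy — an
exact identity by construction). "Cells along an axis" is operationalised
by sampling 201 points along the axis segment, resolving each to the
containing polygon (nearest centroid for boundary-grazing samples, lowest
cell index on ties), with the axis line nudged off exact shared walls by
1e-6 of the transverse extent so that eigenvector roundoff cannot flip
counts. Clones of 3-30 cells are retained, matching the selection applied
to measured clones. Midline assignment is material: midline cells are
those whose centroid carries `i_mid >= 0.5` (ventral vs dorsal by
`i_ven >= 0.5`, stalk excluded), and a clone belongs to a midline domain
if its centre lies within five cells (graph distance over shared polygon
vertices) of it.

## Morphometrics

Staging inverts the exponential growth law `DAI = ln(L'/10 µm) /
(0.018 x 24)`, with `L' = 1.0578 L` for fixed (dehydrated) specimens only;
live-imaged traps are staged uncorrected, which reproduces the published
worked examples (139 µm -> 6.1 DAI; 55 µm -> 4 DAI). Strain rates are
ordinary least squares of log length on time in hours, reported with twice
the standard error. Circumferences are mesh-plane intersections chained
into loops; the sagittal loop is partitioned at the tracked landmark
vertices into ventral midline, dorsal midline and mouth arcs. For
trajectory rates the section is cut once on the first snapshot and its
edge-bound points re-evaluated on later snapshots (a material curve), so
the measures are unaffected by slow off-plane drift. Ventral-midline
straightness is the maximum deviation of the final ventral arc from its
chord, normalised by the chord length.

Resultant strain rates are measured from material quantities: areal rates
from summed material-triangle areas, `ln(A2/A1)/(t2-t1)`; parallel rates as
the time-mean of the instantaneous per-step rate of material segments
re-aligned with the current polarity each step (a material line fixed at
t0 rotates away from the polarity as the tissue shears and would mix in
perpendicular growth).

## Synthetic data

- Growth series: `L(t) = L0 exp(rate x 24 t) exp(eps)`,
  `eps ~ N(0, sigma²)` i.i.d. per observation (multiplicative lognormal
  noise — growth is multiplicative and lengths stay positive), daily
  sampling, defaults rate 0.018 h⁻¹, L0 150 µm, 8 days, sigma 0.05,
  10 subjects.
- Quadrifid fields: glands placed on a 300 µm sphere (or a canvas), near
  pair 4 µm apart, far pair `4 + splay_diff` µm (default 6), far arms
  shortened by `arm_bias` (default 0.2) so DistArms and SumArms agree with
  the ground truth; the axis follows the local stalk-to-mouth reference
  rotated by Gaussian angular noise in the tangent plane.
- Labelled surfaces: a brick mosaic of rectangles whose extents along and
  across the orientation are lognormal with geometric means
  `sqrt(A R)` and `sqrt(A/R)`. This deviates from a stretched centroidal
  tessellation deliberately: per-cell area variance and aspect ratio are
  then controlled exactly (`cv² = e^{2 sigma²} - 1`), which a Voronoi
  tessellation cannot guarantee without weighted seeds. The mosaic
  emulates segmentation-derived cell tables, not cell mechanics.

A green recovery test establishes that the measurement operations are
unbiased against their own noise models at the stated sizes — not that the
generators capture real traps (no gland-size gradients, no hemispherical
gland subpopulation, no segmentation artefacts).

## Numerical choices

- Time step 1 h (per-step strains <= ~3.5 %; a warning fires above 8 %).
  Halving `dt` or refining the mesh one level moves landmark material
  points by under 3 % of trap size (tested).
- Sparse solves: supernodal Cholesky with the symbolic factorisation and
  assembly pattern cached across steps; a failed update falls back to a
  fresh factorisation, and a singular solve raises an error carrying the
  message.
- Element inversion is checked after every step from the wedge Jacobians.
- Quadrifid pairing ties (e.g. perfect crosses) are flagged unpairable
  rather than broken arbitrarily; the assignment threshold (2 µm) is an
  absolute length and is co-scaled in the scale-invariance test.
- Degenerate cells (duplicate vertices, zero area) are excluded from shape
  metrics and never divided.

## Known limitations

- **Stalk-region resultant rates.** This solver reproduces the published
  midline rates closely (central MID areal rate 0.0318 h⁻¹ first-day vs
  0.0318 published; sagittal circumference rate 0.0168 vs 0.0165) but
  resolves the stalk conflicts less completely than the original MATLAB
  framework: the slow-growing polar cap is dragged by membrane shear
  coupling to its fast surroundings, giving a stalk areal rate of ~0.018
  (vs 0.015) in the areal model, a ventral arc rate of ~0.015-0.016
  (vs 0.02), and a stalk parallel rate of ~0.011 (vs 0.0075) in the
  directional model. These values are converged: mesh level 3-5, dt 1-2 h,
  nu 0-0.45, hard vs graded stalk factor, cap radius 15-45 degrees, wall
  thickness 3-30 µm, and fully reduced integration all move them by less
  than 15 % of themselves. The original framework's element formulation
  and elastic constants are not published, so the corresponding acceptance
  checks are left red rather than tuned.
- The mouth is a display region only: no discontinuity, opening, trap door
  or threshold morphogenesis, no lumen pressure, no contact mechanics.
- The model starts at the spherical stage; primordium formation and
  adaxial/abaxial patterning are out of scope.
- Cells are a single surface layer; the inner wall layer and the small
  hemispherical gland cells are not modelled.
- Group summaries report means with standard errors only; no hypothesis
  tests are performed.
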