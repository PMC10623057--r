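---
title: "Fracture mechanics of small-incision cataract surgery wounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fracture mechanics of small-incision cataract surgery wounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In small-incision cataract surgery (SICS) the folded intraocular lens is
pushed through a pre-cut corneal incision, typically about 2.2 mm long, with
an injector tube of diameter d = 1.73 mm. Forcing the incision open to the
injector diameter loads the tissue at the two incision tips; if the energy
release rate (ERR) there exceeds the tissue toughness, the wound tears
beyond the cut. `sicsfract` models this situation for the three incision
shapes used clinically — straight, chevron (two straight arms of length *a*
meeting at an apex with included angle α) and frown (a circular arc of
arclength 2*a* with central angle β) — and asks which shape keeps the tip
ERR lowest at the same required opening.

## Model

The cornea is idealised as a large (60 mm × 60 mm) flat plate in plane
stress, linear elastic, with the incision as a mathematical cut (a *seam*)
of total length 2a = 2.2 mm at its centre. The loading is an equibiaxial
outward normal traction σ₀ on all four edges — the classical mode-I
configuration for the straight cut; for kinked and curved cuts the
edge-parallel component is retained because it then contributes. The applied
load is not a free parameter: it is *calibrated* per shape so that the
opening of the seam at the incision midpoint equals the injector diameter
d. Because the model is linear, calibration is exact — one solve at unit
load gives the opening per unit stress, and the calibrated stress follows
by scaling.

Material constants (defaults, all configurable):

| parameter | default | units | meaning |
|---|---|---|---|
| E | 9.82 | MPa | corneal stiffness at a 3 mm/min strain rate |
| ν | 0.49 | – | Poisson ratio (near-incompressible soft tissue) |
| G_c | 5.40 | kJ/m² | critical energy release rate at the same rate |
| d | 1.73 | mm | injector diameter = required midpoint opening |
| 2a | 2.2 | mm | incision length (arclength for the frown) |

ν is not fixed by the tensile data the stiffness comes from; 0.49 is the
usual near-incompressible choice. For the equibiaxially loaded crack
problem the headline quantities are insensitive to it: the test suite
exercises ν ∈ {0.30, 0.45, 0.49} and the calibrated ERR moves by well under
0.1%.

The stability verdict is Griffith's criterion: the incision is safe when
G ≤ G_c and tears further when G > G_c, with the boundary G = G_c
classified as non-tearing.

For anisotropy studies an orthotropic plane-stress material with ratio
η = E_x/E_y is available (`orthotropic_material()`), mimicking the
direction-dependent stiffness of corneal fibril lamellae: E_y acts along
the vertical symmetry axis of the incision, E_x along the incision. Only
the ratio is physically specified; the remaining constants are completed as
ν_xy = ν√η and G_xy = √(E_x E_y) / (2(1 + √(ν_xy ν_yx))), which reduce
exactly to the isotropic material at η = 1. Results for η ≠ 1 are therefore
trend-level (orderings), not absolute values.

## Meshing: the synthetic-input generator

All inputs are parametric; `build_mesh()` is the package's data generator.
It produces a conforming mixed quadrilateral/triangle mesh with three
structural features the fracture computation relies on:

1. **Seam**: node pairs along the incision are duplicated with coincident
   reference coordinates so the two faces can separate; each tip remains a
   single node.
2. **Spider-web tip rings**: each tip carries `n_rings` (default 10)
   concentric rings — a triangle fan inside, quadrilateral annuli outside,
   radii in geometric progression `r_inner · ring_growth^(k-1)` — each ring
   doubling as one contour-integral domain.
3. **Graded far field**: a rectilinear grid grows geometrically (ratio
   `grade_ratio`) from the incision scale to `far_field_size` at the plate
   boundary.

The web is stitched to the grid through a square transition patch, so the
whole construction is block-structured. Chevron and frown geometries are
obtained by building the mesh for a straight reference incision and
applying a smooth in-plane map that carries reference arclength stations
exactly onto the parametric path, decays to the identity away from the
incision, and provably preserves element orientation for the angle ranges
admitted (kinks up to 30°, arcs up to 50°); every generated mesh is
additionally checked for positive corner Jacobians. `snap_seam_nodes()`
provides the usual post-generation hygiene (projecting stragglers onto the
path, merging near-coincident duplicates) and is a no-op on well-formed
meshes.

Mesh defaults — `r_inner = a/150`, `ring_growth = 1.30`, `n_spokes = 24`,
`grade_ratio = 1.18`, `far_field_size = width/10` — were fixed by a
grid-independence study against the closed-form centre-crack solution
(`analytic_center_crack()`): at these settings the FE energy release rate
matches the infinite-plate formula to ~0.7% (part of which is the genuine
finite-plate correction), the midpoint opening to ~0.25%, the ring-to-ring
scatter of the contour integrals is ~0.1%, and one full solve
(~9,000 elements, ~18,000 unknowns) takes well under a second. Halving
`r_inner` and `far_field_size` moves the calibrated ERR by less than 1%,
which is the refinement criterion the test suite enforces.

What the generator emulates is the *mechanical* situation — a planar
incision in a homogeneous sheet under far-field tension. What it does not
emulate about real corneas: surface curvature and the 3D tunnel
architecture of the wound, the layered and regionally varying fibril
anisotropy, nonlinear/viscoelastic response beyond the single (E, G_c)
pair, and contact between the wound faces. Passing tests therefore
establish correctness of the stated idealisation, not clinical validity.

## Energy release rate

`err_at_tip()` evaluates the J-integral in its equivalent-domain form,

J = ∫_A (σᵢⱼ ∂uᵢ/∂x₁ − W δ₁ⱼ) ∂q/∂xⱼ dA,

in local tip coordinates with x₁ along the virtual crack-extension
direction. For ring k the weight q is 1 on nodes inside ring k−1 and ramps
to 0 across ring k, so each spider-web ring yields one contour value.
Rings 1–3 are discarded as tip-affected; the reported G is the arithmetic
mean of rings 4–10 and the relative standard deviation over those rings is
the convergence diagnostic (results with scatter ≥ 2% are flagged).

At a chevron or frown tip the extension direction is the local tangent
(self-similar straight-ahead advance). Mode mixity at the kinked tip is not
decomposed; the total G is reported, matching the single-toughness Griffith
test. For the straight centre crack the pipeline reproduces
G = πσ₀²a/E within 1%, and G scales exactly quadratically in the load — both
are enforced property tests.

## Protocols

* `calibrate_load()` — the unit-solve/scale calibration, with a confirming
  solve (`|opening − d|/d < 1e-6`).
* `sweep_chevron()` / `sweep_frown()` — calibrated ERR across the angle
  grids (120–180° and 5–50°, 5° steps with 1° refinement around the
  detected minimum; β is admitted down to 1° so the continuity of the frown
  family into the straight limit is testable). Crossings of G_c are
  located by linear interpolation between grid points.
* `critical_length()` — inverts G(2a) = G_c at calibrated load by root
  bracketing with a full remesh and recalibration per iterate (tolerance
  1 µm on 2a). Because the opening is held at d, G falls with length —
  shorter incisions tear — and for the straight incision the closed form
  2a* = πEd²/(8G_c) ≈ 2.14 mm anchors the test.
* `orthotropy_table()` — calibrated chevron ERR over η × α.
* `compare_shapes()` — percent ERR change of the best chevron and best
  small-angle frown relative to straight, (G_straight − G)/G_straight × 100.

## Numerical choices and tie-breaks

* Elements are fully integrated bilinear quadrilaterals (2×2 Gauss) plus
  constant-strain triangles in the fan; no reduced integration, hence no
  hourglass control. The contour-based G is insensitive to this choice at
  convergence.
* The full plate is modelled rather than a symmetry half — this keeps the
  chevron apex seam unconstrained and makes the mirror symmetry of the
  solution an *observable* test rather than an assumption.
* Rigid-body motion is removed by pinning the mid-left boundary node and
  the vertical motion of the mid-right node (a single pinned point would
  leave rotation free in a pure-traction problem).
* Chevron orientation (apex up) and frown bow (up) are fixed conventions;
  for an isotropic material under equibiaxial load the choice is
  immaterial, which is why curving "up" (smile) and "down" (frown) need not
  be distinguished here.
* The chevron apex is a kink: the midpoint opening there uses the bisector
  normal, and the apex is always a seam vertex (even segment counts are
  enforced).
* Critical-length brackets come from the near-inverse scaling G ∝ 1/a at
  fixed opening, then `uniroot` refines.

## Calibration sensitivity and reproduction limits

Because the load enters G quadratically, the calibrated ERR inherits twice
the relative error of any opening (compliance) estimate: a 2% error in the
computed midpoint opening becomes ~4% in G. This makes the calibrated
sweep curves a demanding target: independent implementations that agree
closely on G at a *given* load can still differ by several percent after
each recalibrates against its own computed opening. In this implementation
the angle sweeps respond smoothly to shape: the chevron curve rises
monotonically (quadratically in the kink angle) from the straight limit,
and the frown curve falls gently with curvature, with no interior optimum
at the default conditions. The test suite records these computed curves
as-is rather than forcing agreement with any externally tabulated optimum.

## Known limitations

No crack-face contact (compressive loads are flagged, not resolved); no
K_I/K_II decomposition; small-strain kinematics; rate effects collapsed
into the single (E, G_c) pair; 2D flat geometry. The meshing supports
exactly one incision in a rectangular plate — it is a study generator, not
a general mesher.
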