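---
title: "A plane-stress finite-element model of internal urethral sphincter opening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A plane-stress finite-element model of internal urethral sphincter opening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Primary bladder neck obstruction (PBNO) is a failure of the internal urethral
sphincter to open during voiding. A proposed laser treatment drills a small
number of through-holes (radius 0.5 mm) into the fibrotic part of the
sphincter instead of incising it, with the aim of restoring opening capacity
while preserving the muscle ring. `sphincterFE` models the mechanics of that
intervention: a two-dimensional cross-section of the sphincter is pressurised
from the lumen, and the deformed open area is compared across a sane
configuration (`P0`), a fibrotic configuration (`H0`), and fibrotic
configurations with 3-7 drilled holes (`H3`..`H7`, plus a staggered
six-hole variant `H6b`).

The two quantitative outcomes are the opening loss and the opening
deformation recovery,

$$\delta_l = 100\,\frac{A(H_i) - A(P0)}{A(H0)}, \qquad
  \delta_r = 100\,\frac{A(H_i) - A(H0)}{A(H0)},$$

where $A(\cdot)$ is the deformed lumen cross-sectional area at the working
intraluminal pressure of 1960 Pa (about 20 cm H2O, a typical voiding
pressure).

## Geometry

No measured geometry is available for the modelled section, so the package
builds a parametric, synthetic stand-in:

* a circular lumen (radius `lumen_radius`),
* a stiff dense-connective ring around it (the transitional epithelium,
  thickness `epithelium_thickness`),
* a spongy stratum (lamina propria) out to a smoothly non-circular outer
  boundary (`outer_radius`, `outer_waviness`), divided into four parts by
  four thin open slits (width `slit_width`), and
* two 1-mm ligaments ("bounds") on the horizontal axis connecting the upper
  and lower spongy parts.

The two lower spongy parts are fibrotic in all `H*` cases; fibrosis is a
tenfold scaling of the deviatoric stiffness of the spongy material. Surgical
holes are placed on an arc at 60% of the fibrotic thickness (or on two
radially offset arcs for the staggered variant), uniformly in angle over the
two lower quadrants while keeping a positive clearance from every tissue
boundary and from the bottom slit. Two modelling choices here were genuinely
open and are decisions of this package:

* The four-part division is realised as open notches of finite width
  (0.3 mm) rather than zero-width cracks; at these widths the two are
  mechanically equivalent, and notches avoid duplicated-node crack meshing.
* The slit pattern is vertical (top/bottom, full spongy depth) plus
  horizontal (left/right, starting one bound length outside the ring), which
  realises "four parts connected by two 1-mm bounds" with the bounds as
  radial ligaments adjacent to the ring.
* The two fully fixed points of the model sit on the outer boundary at the
  corners of the top and bottom slits (the vertical axis itself is void);
  a sensitivity test in the suite verifies the opening metrics are
  insensitive to moving the pins.

## Material model

All three tissues use a five-parameter Mooney-Rivlin strain energy

$$W = C_{10}(\bar I_1-3) + C_{01}(\bar I_2-3) + C_{20}(\bar I_1-3)^2
    + C_{02}(\bar I_2-3)^2 + C_{11}(\bar I_1-3)(\bar I_2-3)
    + \tfrac{1}{d_1}(J-1)^2,$$

with $\bar I_1 = J^{-2/3} I_1$, $\bar I_2 = J^{-4/3} I_2$ the isochoric
invariants of $C = F^\mathsf{T} F$ and $J = \det F$. The volumetric penalty
$1/d_1 (J-1)^2$ with $d_1 = 8\times10^{-7}$ 1/Pa gives an initial bulk
modulus $2/d_1 = 2.5$ MPa, i.e. near-incompressibility relative to the
initial shear moduli ($\mu_0 = 2(C_{10}+C_{01})$: 10.3 kPa for the dense
connective ring, 343 Pa for the spongy stratum, 3.4 kPa fibrotic).

The deviatoric part is evaluated on the *isochoric* invariants by default.
The printed form of this energy is sometimes written on total invariants;
that variant is available as `form = "total"` in `mooney_rivlin5()`, but it
carries a nonzero hydrostatic stress $2(C_{10}+2C_{01})$ at the reference
state, which contradicts a stress-free undeformed configuration (and the
behaviour of the commercial element family this model descends from), so the
isochoric form is the default. At $J = 1$ the two coincide.

Plane stress is enforced pointwise: at every quadrature point the
through-thickness stretch $\lambda_3$ solves $S_{33}(\lambda_3) = 0$ by a
guarded Newton iteration (bisection-backed, residual tolerance
$10^{-10}\mu_0$, root sought in $\lambda_3 \in (0.05, 20)$), and the
condensed in-plane tangent includes the $\partial\lambda_3/\partial C$ term.
All stress and tangent expressions are analytic; the test suite verifies
them against finite differences of an independently coded scalar energy
(tolerance $10^{-6}$ relative).

## Discretisation and solver

The mesh combines a structured polar grid for the thin stiff ring (exact
thin-layer refinement, well-shaped elements) with an unstructured
distmesh-style triangulation of the spongy stratum (graded hexagonal seed
lattice, rejection-thinned against the size field; Delaunay connectivity;
long-edge splitting, crowded-node removal and Laplacian smoothing). Elements
are 3-node constant-strain triangles with two displacement components per
node; in plane stress the through-thickness stretch absorbs the volumetric
constraint, so these elements do not lock despite near-incompressibility.
The target edge length is `h_fine` in the ring, in a band of one ring
thickness around it and around every hole, grading to `h_coarse` elsewhere.
The generator guarantees a minimum element angle of 20 degrees, maximum edge
lengths bounded by the size field, and is fully deterministic.

Equilibrium is total-Lagrangian with a follower pressure on the deformed
lumen boundary (the load stiffness is included, making the tangent mildly
non-symmetric) and a direct sparse LU solve. Two drivers exist:

* plain incremental load stepping with Newton-Raphson, line search and
  adaptive increment halving (used by the verification benchmarks), and
* **area-controlled continuation** (used by `solve_case()` and
  `sweep_pressure()`): the deformed lumen area is the continuation
  parameter, the pressure is an extra unknown, and the bordered system
  (equilibrium + area constraint) is solved by Newton with a shared
  factorisation. States at the requested pressures are extracted where the
  path first crosses them, with a secant refinement in the area parameter.

Area control exists because the pressure-area response of this structure is
strongly nonlinear and passes close to (and, for compliant geometries,
through) a pressure limit point, where load control stalls. Near local
instabilities the driver can additionally apply a small pseudo-viscous
stabilisation (a restoring force proportional to the displacement increment)
and then relaxes the converged state back to the unmodified equilibrium;
any residual stabilisation magnitude is recorded with the result.

On detected element distortion (displaced internal angle above 160 degrees,
strict, or inversion) the increment is rejected; if the minimum step still
distorts, the mesh is regenerated at 0.75 times the element size and the
load program restarts from zero. Mid-solve remeshing with state transfer is
intentionally not implemented: at the problem sizes used here the
regenerate-and-restart policy reaches the same end states with far less
machinery.

## Calibration of the default geometry, and a known limitation

The geometric dimensions of the modelled section are not published, so the
package's defaults are free parameters that were calibrated once, before
freezing, against two requirements: a plausible bladder-neck anatomy, and a
sane-case open area at 1960 Pa within 20% of 18.09 mm^2. The shipped
defaults are `lumen_radius = 2.0` mm, `epithelium_thickness = 2.0` mm,
`outer_radius = 6.8` mm, `outer_waviness = 0.04`; they give
$A(P0) \approx 17.6$ mm^2 at 1960 Pa, and every case of the battery and the
full 196-2584 Pa sweep converge.

One genuine limitation must be stated plainly. In this two-dimensional
plane-stress idealisation, any geometry soft enough for the spongy stratum
to dominate the opening runs into a membrane wrinkling instability well
below 1960 Pa: the flanks of the slits go into in-plane compression, and a
membrane has no bending stiffness to set a wrinkle wavelength, so the
computation terminates by element collapse at a deformed-to-undeformed area
ratio of about 1.8 regardless of mesh size. A large opening-loss contrast
between the sane and fibrotic configurations (tens of percent) lives exactly
in that post-instability regime. The calibrated defaults therefore sit in
the ring-stiffness-dominated regime, where the whole study program runs
stably but the fibrosis-induced opening loss is on the order of only a
percent, and the per-hole recovery is correspondingly small. The suite
asserts the large-contrast expectation anyway and the corresponding check
fails by design rather than being weakened; treat the absolute loss/recovery
magnitudes from this model as qualitative. The hole-count trend remains
meaningful because meshes of different cases share their point clouds away
from the holes, so case differences are localised to the drilled region.

## Post-processing

The deformed lumen area is the shoelace area of the deformed boundary
polyline (self-intersection checked). Principal Cauchy stresses come from
the per-element eigendecomposition of $\sigma = F S F^\mathsf{T}/J$;
principal strains use the logarithmic (Hencky) measure by default, with
Green-Lagrange behind a flag - the reporting measure is a package decision,
as the original study does not state one. Intraluminal profiles sample the
elements adjacent to the lumen boundary, ordered clockwise by deformed arc
length and split into physiological (upper) and fibrotic (lower) arcs at the
horizontal axis of the reference configuration. Areas are reported in mm^2
to two decimals; losses and recoveries in percent to two decimals.

## Problem sizes and tolerances used by the checks

* Default battery mesh: `h_coarse = 0.45` mm, `h_fine = 0.225` mm (about
  12,000 elements per case), used by both the shipped acceptance script and
  the test-suite battery. The refinement study (annulus benchmark) shows the
  inner-boundary solution changes by well under 0.5% under a twofold
  refinement. The paper-style sizes (0.1/0.05 mm) are one config switch
  away.
* Newton tolerance: residual below $10^{-8}$ of the external load norm;
  quadratic convergence near the solution is asserted on the annulus
  benchmark.
* The thick-walled-cylinder (Lame) benchmark at 1 Pa agrees with the
  analytic plane-stress displacement to 0.3% at the default benchmark mesh
  (tolerance 2%).
* Verification can be re-run at any time with `verify("fast")` (constitutive
  and single-element oracles, seconds) or `verify("full")` (adds Lame and
  the refinement gate, about a minute).

## What the synthetic geometry does and does not capture

The generator reproduces the topology of the modelled section - lumen, stiff
ring, four-part spongy stratum with bounds, fibrotic lower half, drilled
holes - with idealised circular arcs and a smooth outer profile. It does not
capture the irregular histological outline, tissue anisotropy,
viscoelasticity, active muscle tone, self-contact of a collapsing lumen, or
any out-of-plane (3D) effect; passing tests on this geometry demonstrate
correctness of the mechanics and the trends across configurations, not
patient-specific accuracy.
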