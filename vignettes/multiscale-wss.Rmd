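---
title: "Multiscale quantification of wall shear stress in irregular scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale quantification of wall shear stress in irregular scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poreflow)
```

## The problem

Perfusion bioreactors drive culture medium through porous scaffolds to
mechanically stimulate seeded cells; the stimulus is the wall shear stress
(WSS) that the creeping flow exerts on the pore walls, typically a few to a
few tens of mPa. Salt-leached protein scaffolds (e.g., silk fibroin) have
highly irregular, non-repetitive pores, so no unit-cell shortcut exists, and
resolving the whole scaffold at pore resolution is prohibitively expensive.
`poreflow` implements a multiscale route:

1. **Micro:** solve pore-scale Stokes flow on one or more representative
   volume elements (RVEs) and homogenize each to a Darcy permeability
   $\kappa$ via $Q = \frac{\kappa A}{\mu}\frac{\Delta p}{H}$.
2. **Macro:** solve the scaffold-in-channel at continuum scale, with the
   scaffold as a homogeneous porous medium of permeability $\bar\kappa$
   (arithmetic mean over RVEs), giving the pressure pair
   $(p_\mathrm{top}, p_\mathrm{bottom})$ on the scaffold faces.
3. **Micro again:** re-solve each RVE driven by its local pressure pair and
   evaluate the WSS field $\tau = \mu\,\partial v_t/\partial n$ on the
   pore walls.

Because every RVE spans the full scaffold height, the vertical pressure drop
of the macro model maps directly onto the micro model; lateral cut faces are
treated as symmetry planes (zero normal velocity, zero normal gradient of
tangential velocity), which suppresses inter-RVE flow and is the method's
main approximation — its cost is quantified by the validation protocol
below.

## Voxel-native design

The entire chain operates on voxel lattices (micro-CT-style data), not on
body-fitted meshes. Geometry processing (Gaussian filtering, window
segmentation, iterated blur-and-rethreshold label smoothing), RVE cropping,
and the flow solve all share one discretisation, which makes every stage
deterministic and testable and removes meshing as a failure mode. The
equivalent of a mesh-size choice is the voxel size itself; the analytic-duct
refinement tests (10, 20, 40 voxels across a channel) document how
discretisation error decays.

Label images use 1 = fluid, 0 = solid; z is the perfusion axis; physical
boxes are half-open `[lo, hi)` in micrometres.

## The pore-scale solver

Incompressible Stokes flow is discretised with a marker-and-cell staggered
finite-volume scheme: face-normal velocities between pairs of fluid voxels,
pressures at fluid cell centres. Solid voxels are excluded from the unknown
set, so wall-normal velocities vanish identically and wall-tangential
neighbours enter through reflecting ghost values ($-u$), placing the no-slip
plane half a voxel from the face centre (second-order at flat walls).
Inertia is dropped deliberately: at 500 µm/s through ~100 µm pores the pore
Reynolds number is ~0.1, and linearity buys exact superposition — the test
suite exploits this with scaling and symmetry properties that a nonlinear
solver could not satisfy to 1e-8. The solver reports Re and warns above 1.

Boundary conditions:

* **Velocity inlet** — uniform plug on the inlet plane with zero tangential
  velocity. Configured inlet velocities are *superficial* (empty-channel)
  values: the plug value is scaled by the inlet-plane fluid fraction so a
  domain carries exactly $u_s A$. This keeps the micro, macro and direct
  models at the same perfusion rate, which matters when their inlet
  porosities differ.
* **Pressure inlet/outlet** — uniform normal traction with free tangential
  slip. Discretely, prescribed pressures act at ghost centres half a voxel
  outside the box; pressure-drop accessors therefore measure gradients from
  the interior profile rather than differencing the boundary values.
* **Lateral faces** — `symmetric` (RVE cut planes) or `no_slip` (outer
  walls of a direct model).

The symmetric saddle-point system (momentum rows scaled by $h^2$) is solved
either by a pressure Schur-complement CG with a Cholesky-factorised viscous
block (small systems; near-exact, used at oracle tolerances down to 1e-12)
or by full-system MINRES with block-Jacobi scaling (large systems; no
factorisation memory, iteration count sets the cost). The automatic
dispatch prefers MINRES above ~120k unknowns at engineering tolerances
and above ~250k unknowns at oracle tolerances. The
convergence criterion is the relative RMS discrete mass residual
(default `tol = 1e-4`); momentum is satisfied to factorisation accuracy on
the Schur path and tracked explicitly on the MINRES path. The solve is
re-tightened automatically if the global inlet/outlet flux budget is not
within 10 times `tol`.

## Permeability

$\Delta p$ in Darcy's law is the least-squares slope of the plane-averaged
pressure profile over the central 80% of the height, times $H$. Differencing
the end planes instead would fold plug-inlet redistribution losses into
$\kappa$ and bias it low; the slope estimate is exact for the linear mean
profile of developed flow and is what the downstream macro model assumes.
$A$ is the full cross-section (solid + fluid), so $\kappa$ relates
superficial velocity to the pressure gradient. Aggregation over RVEs is the
arithmetic mean — the consistent choice for parallel full-height columns
(harmonic/geometric means would suit serial or log-normal structures).

## The macro model

Rather than coupling separate Darcy and Navier–Stokes domains with explicit
interface conditions, the macro model is a single-domain Brinkman
penalization: $\mu\nabla^2 v - (\mu/\kappa_{loc})v - \nabla p = 0$ with
$\kappa_{loc} = \bar\kappa$ in the scaffold region and the drag off in the
free fluid. Mass-flux continuity across the interface holds by construction,
and in the creeping regime the two formulations coincide. The same staggered
assembly is reused with a per-cell drag term (face coefficients from the
mean adjacent inverse permeability), so one solver serves both scales.

Geometry: a cylindrical lumen (or a square duct, the natural counterpart of
box-shaped synthetic scaffolds and of direct models with no-slip side
walls) with entrance/exit free-fluid segments defaulting to one scaffold
height each — their exact length is not critical because the free-fluid
pressure gradient is orders of magnitude below the porous one. Default
resolution is 20 cells over the porous height; the Brinkman wall layer
($\sqrt{\kappa}\sim$ 10–30 µm) is thinner than a macro cell, so wall effects
are represented at one-cell resolution — adequate here because only
plane-averaged face pressures are consumed. The face pressures are obtained
by linear extrapolation of the two adjacent interior porous layers
(exact for the linear Darcy profile), optionally restricted to an RVE
footprint.

With the worked-example inputs ($\bar\kappa = 7.47\times10^{-10}$ m²,
$\mu = 1$ mPa s, 500 µm/s, $H = 1$ mm) the model yields
$\Delta p \approx 0.70$ Pa, a few percent above the unbounded-Darcy value
$\mu v H/\kappa = 0.669$ Pa because the no-slip walls force the core to
carry slightly more than the mean flux.

## WSS recovery

WSS elements live on the staircase wall faces, but their evaluation
accounts for the true local surface orientation: the outward normal of
each face is estimated from the gradient of a Gaussian-smoothed solid
indicator ($\sigma = 1.2$ voxels), the tangential speed is sampled by
trilinear interpolation at 2, 3.5 and 5 voxels along the inward normal,
and a quadratic profile fitted through the samples is differentiated at
its own near-wall root. Letting the profile locate its root absorbs the
sub-voxel offset between the geometric surface and the effective no-slip
plane of the staircase discretization, which one-sided difference formulas
amplify; starting the samples two voxels out skips the corner-retarded
staircase layer. The scheme is exact for plane-Poiseuille and tube
profiles, and each face carries its projected area (voxel face area times
$|\hat n \cdot \hat e|$), so total wall areas estimate the smooth
interface area rather than the 4/π-inflated staircase area. Against the
analytic ducts this evaluates mean WSS within ~3% (plates) and ~4%
(tubes at 16 voxel radii); plain face-normal one-sided differences are
10–20% low on oblique walls, which is why they are not used. Histograms
are area-weighted by default (count weighting available): surface-area
fractions, not face counts, are the biologically meaningful measure.
Default binning is 5 mPa over [0, 100] mPa plus an overflow bin, spanning
the reported stimulation windows (0.11–10, 0.55–24, 10–30 mPa).

## The synthetic scaffold generator

No public micro-CT scan accompanies the method's original application, so
validation runs on synthetic scaffolds: white noise smoothed with a
periodic Gaussian kernel and thresholded at the porosity quantile. The
kernel width is calibrated from level-crossing theory so that the mean
intercept (chord) length of the fluid phase equals the requested mean pore
diameter. Non-spanning fluid components are converted to solid and the
threshold re-adjusted until the percolating porosity is within ±0.02 of
target; generation fails explicitly rather than return a blocked geometry.
The result reproduces the salient features of salt-leached scaffolds —
irregular, non-repetitive, fully interconnected pores with controllable
porosity and pore size. It does *not* emulate anisotropy, pore-size
bimodality, strut-surface texture, or scan noise, so passing validation
here demonstrates the method's internal consistency on irregular media, not
agreement with any particular physical scaffold.

Default study conditions (used by the validation workflow and the
acceptance script): porosity 0.8, voxel size 10 µm, scaffold cubes of
64 voxels, central RVE of half the footprint, superficial inlet velocity
500 µm/s, medium viscosity 1.0 mPa s and density 1000 kg/m³. The default
mean pore diameter is 100 µm, chosen to preserve the scale separation the
method assumes: about 6 pores over the scaffold height and a pore-to-RVE
ratio of ~0.3, the same ratios as a 1–2 mm silk-fibroin scaffold with
150–300 µm pores. With coarser pores (few pores per RVE), the RVE is no
longer representative: per-seed permeability estimates scatter, and
entrance effects reach deep into the column. That regime stresses the
method beyond its stated assumptions and is not part of the default
conditions.

## Validation protocol

For a scaffold small enough to solve directly, the package compares:
multiscale WSS on the central RVE (symmetric laterals, pressure-driven)
against the direct solve of the whole scaffold (velocity inlet, no-slip
outer walls) restricted to the same footprint. The comparison reports the
Pearson correlation between paired area-weighted histogram bins (per-element
pairing across different flow solutions is not meaningful), per-subregion
average WSS in five concentric square annuli counted inward from the RVE
boundary (width defaulting to footprint-side / 10, so the annuli tile the
half-footprint), and percent errors with the direct solution as reference.
The boundary subregion is where the symmetric-lateral approximation bites,
and it shows the largest disagreement for most seeds; histogram correlations
on 64-voxel scaffolds are typically 0.95–0.98.

## Numerical choices and edge cases

* 6-connectivity defines fluid percolation and wall faces, matching the
  staggered stencil; trapped (non-percolating) pores are removed and
  reported, as they carry no flow and would make the system singular.
* Degenerate inputs fail loudly: blocked domains, non-percolating
  geometries, out-of-bounds RVE boxes, empty segmentations (warning, valid
  single-phase image), label-smoothing volume collapse (>10% guard).
* Determinism: the generator restores the global RNG state; solver paths
  are iteration-deterministic; re-running a pipeline with the same seed and
  config reproduces summary tables bit-identically.
* Problem sizes in the shipped tests are chosen for single-CPU runs:
  analytic ducts at 10–40 voxels across, scaffolds of 16³–64³, macro grids
  of ~20–30³. The full-scale configurations (150³ and 500×500×200 voxels)
  are provided as YAML examples and run the same code paths.

## Known limitations

* WSS on staircase walls converges only O(h) for oblique surfaces; the
  refinement tests quantify the residual (a few percent at 16–20 voxels
  per feature, ~10% at 10). Features below ~8 voxels are unreliable.
* The macro model resolves Brinkman wall layers at one-cell resolution;
  only plane-averaged pressures should be consumed from it.
* Symmetric lateral RVE boundaries suppress inter-RVE flow; errors
  concentrate near the RVE boundary and grow when pores are not small
  compared to the RVE.
* Creeping flow only: the Reynolds audit warns when inertia would matter.
* No cell-seeded (partially occluded) geometries, transient protocols,
  non-Newtonian rheology, or fluid–structure interaction.

## Worked example

```{r example}
library(poreflow)

scaffold <- generate_scaffold(porosity = 0.8, mean_pore_diameter = 100,
                              shape = c(64, 64, 64), voxel_size = 10,
                              seed = 1)
run <- run_multiscale(scaffold)
print(run)

direct <- run_direct(scaffold)
report <- compare_wss(run$wss[[1]], direct$roi_wss, run$rves[[1]])
print(report)
```
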