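# poreflow

Multiscale, voxel-native computational fluid dynamics for the
micro-fluidic environment inside porous tissue-engineering scaffolds.

## Who this is for

Tissue engineers and computational biomechanics researchers who perfuse
cell-seeded scaffolds in flow bioreactors and need to know the wall shear
stress (WSS) their cells actually experience. For scaffolds with highly
irregular pores (salt-leached silk fibroin, collagen-GAG, ...) there is no
repeating unit cell, and resolving a whole multi-millimetre scaffold at
pore resolution is out of reach on a desktop. `poreflow` implements the
multiscale alternative: homogenize pore-scale flow to a permeability, solve
the scaffold-in-channel at continuum scale, and hand the resulting pressure
boundary conditions back to the pore scale to recover the WSS field.

## The model

* **Pore scale (micro):** incompressible creeping (Stokes) flow on the
  voxelized pore space, no-slip on pore walls,
  `div v = 0`, `mu lap(v) = grad p`. Lateral cut faces of a
  representative volume element (RVE) are symmetry planes
  (`v_n = 0`, `d v_t / d n = 0`).
* **Homogenization:** Darcy's law `Q = (kappa A / mu) (dp / H)` turns each
  solved RVE into a permeability `kappa` (m^2); several RVEs are averaged
  arithmetically.
* **Macro scale:** a single-domain Darcy–Brinkman (penalized) model of the
  bioreactor channel containing the homogenized scaffold,
  `mu lap(v) - (mu / kappa_loc) v - grad p = 0`, which degenerates to
  Navier–Stokes-in-the-creeping-limit in the free fluid and to Darcy flow
  in the scaffold, with interface mass-flux continuity by construction.
  Its output is the pressure pair `(p_top, p_bottom)` on the scaffold
  faces.
* **WSS:** on every fluid–solid voxel face,
  `tau = mu * d v_t / d n` (tangential traction magnitude, reported in
  mPa), with area-weighted histograms, stimulation-band surface fractions
  (e.g. the 10–30 mPa mineralization window), and boundary-subregion
  averages.

A direct (single-scale) solver for small scaffolds and a comparison
protocol (paired-histogram Pearson correlation, subregion percent errors)
quantify the cost of the multiscale approximation. Everything runs on
binary voxel images — synthetic scaffolds from the built-in correlated
random-field generator, or micro-CT-style TIFF/NRRD stacks.

## Worked example

```r
library(poreflow)

scaffold <- generate_scaffold(porosity = 0.8, mean_pore_diameter = 100,
                              shape = c(64, 64, 64), voxel_size = 10,
                              seed = 1)
run <- run_multiscale(scaffold)
print(run)
#> <multiscale_run> 1 RVE(s), kappa_bar = 6.7611e-11 m^2
#>   macro dp = 4.844 Pa (p_top 4.876, p_bottom 0.03125)
#>   RVE 1: kappa 6.761e-11 m^2, mean WSS 37.7 mPa

direct <- run_direct(scaffold)
report <- compare_wss(run$wss[[1]], direct$roi_wss, run$rves[[1]])
print(report)
#> <validation_report> Pearson r = 0.971 (histogram weights)
#>   region (outermost -> innermost) average WSS [mPa] and % error:
#>    region 1: multiscale 32.3, direct 40, error 19.35%
#>    region 2: multiscale 38.9, direct 40.8, error 4.64%
#>    region 3: multiscale 41.7, direct 43.1, error 3.12%
#>    region 4: multiscale 42.5, direct 44.4, error 4.23%
#>    region 5: multiscale 41.1, direct 44, error 6.48%
```

Reading this: the 64^3-voxel (0.64 mm) synthetic scaffold at porosity 0.8
homogenizes to `kappa ~ 6.8e-11 m^2`; driving the channel at a superficial
500 um/s costs ~4.8 Pa across the scaffold; the pore walls of the central
RVE then see a mean WSS of ~38 mPa. The multiscale field agrees with the
direct whole-scaffold solve almost bin-for-bin (r = 0.97), and the
disagreement concentrates in the outermost subregion, where the symmetric
lateral boundaries of the RVE suppress the lateral flow the direct model
resolves — the method's known, localized approximation.

A command-line wrapper covers the same workflows
(`generate | permeability | macro | wss | multiscale | direct | validate`):

```sh
Rscript inst/cli/poreflow.R validate --seed 1 --size 64 --out out/
Rscript inst/cli/poreflow.R multiscale --config inst/extdata/paper_large.yml --out out/
```

Example configurations for a 1.5 mm validation-scale scaffold and a
5 mm x 2 mm bioreactor scaffold (3 mL/min, 3x3 RVEs of 0.4 mm) ship in
`inst/extdata/`.

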