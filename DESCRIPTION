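Package: poreflow
Title: Multiscale Voxel-Based Flow and Wall Shear Stress Analysis for
    Tissue-Engineering Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the micro-fluidic environment inside porous
    tissue-engineering scaffolds under medium perfusion. Provides a
    synthetic generator for irregular interconnected pore networks, voxel
    image I/O (TIFF stacks, NRRD), a staggered-grid finite-volume Stokes
    solver for pore-scale creeping flow, Darcy permeability homogenization
    over representative volume elements, a Darcy-Brinkman macro model of
    the scaffold inside a bioreactor channel, wall shear stress (WSS)
    recovery on the fluid-solid interface, and a multiscale pipeline that
    hands macro pressures back to the pore scale, with a validation
    protocol comparing multiscale against direct pore-scale solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
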