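Package: vistr
Title: Visualisation and Analysis of Chemical Shielding Tensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nucleus-independent chemical shift (NICS) analysis and
    3D visualisation of chemical shielding tensors. Generates labelled ghost-atom
    probe points (ring centres, offsets above ring planes, bond midpoints, line
    scans, planar grids), parses shielding-tensor blocks from quantum-chemistry
    logs, decomposes generally non-symmetric 3x3 shielding tensors into principal
    axes and eigenvalues, extracts isotropic and directional NICS values, and
    renders the decompositions as oriented dumb-bell glyphs (VMD TCL scripts,
    OBJ meshes, JSON scenes). A classical ring-current simulator (point-dipole
    and Biot-Savart current loops) and a numerical diamagnetic (Lamb) integrator
    over cube-format electron densities make the full pipeline testable without
    a quantum-chemistry engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
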