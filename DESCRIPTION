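Package: gistwater
Title: Grid Inhomogeneous Solvation Theory and Automated Water Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-voxel solvation thermodynamics (grid inhomogeneous
    solvation theory, GIST) from a restrained-solute explicit-water
    trajectory, places and orients individual water molecules from the
    resulting density and free-energy grids, ranks them by solvation free
    energy and distance to the solute, and exports microsolvated
    solute-water clusters for quantum chemical follow-up. Includes a
    synthetic-trajectory generator with known hydration hotspots for
    validation, radial distribution functions, and OpenDX/CSV grid export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
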