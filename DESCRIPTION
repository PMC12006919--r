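Package: aenm
Title: Augmented Elastic Network Simulation of Coarse-Grained Biomolecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic, scriptable simulation engine for coarse-grained
    particle systems held together by Hookean spring networks and augmented
    with non-bonded (Lennard-Jones, Coulomb), precomputed grid-field,
    implicit planar membrane, and surface-accessibility energy terms.
    Structures are read from PDB or PQR files and reduced to one bead per
    residue; damped deterministic dynamics with optional user steering
    forces propagate the system while streaming observables (per-term
    energies, membrane insertion depth and tilt, solvent-accessible surface
    area). Includes OpenDX scalar-grid I/O with trilinear interpolation, a
    deterministic golden-spiral Shrake-Rupley surface-area routine, a cell
    grid for neighbour searches, a steepest-descent minimizer, a YAML
    configuration front end, and generators for self-contained demonstration
    systems (mechanical deformation, guided docking, membrane insertion).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
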