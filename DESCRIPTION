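Package: pocketframe
Title: Grid-Based Binding-Pocket Volumes and Activation Geometry for GPCR
    Transmembrane Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structural analysis of G protein-coupled
    receptor (GPCR) transmembrane (TM) bundles. Computes the solvent-accessible
    ligand-binding cavity volume of a membrane-aligned receptor on a regular 3D
    grid bounded laterally by polygons through the seven TM helix centers,
    below by the C-alpha of the conserved toggle-switch tryptophan (generic
    position 6.48), and above by the most extracellular TM residues, with grid
    points clashing with protein atoms removed. Also measures activation
    geometry between paired receptor states: per-residue C-alpha displacements
    after Kabsch superposition, helix-axis tilt angles, chi1 rotamer classes,
    protein-peptide contacts, and peptide insertion depth. Includes a
    synthetic-structure generator producing idealized TM bundles with known
    ground-truth geometry, plus a Monte-Carlo volume oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
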