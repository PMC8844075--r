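# pocketframe

Grid-based ligand-binding cavity volumes and activation geometry for GPCR
transmembrane (TM) bundles.

## What it does, and for whom

Structural biologists comparing inactive and active states of a class A
G protein-coupled receptor need numbers for statements like "the binding
cavity expands", "the extracellular helix tips move outward", or "the
peptide inserts this deep". `pocketframe` computes those numbers from
atomic coordinates (PDB or mmCIF):

* **Cavity volume.** With the receptor membrane-aligned (z = membrane
  normal), a regular 3D grid of spacing *s* covers the structure. A point
  **x** is cavity iff

  1. *z*(W^6.48 Cα) ≤ *z*(**x**) ≤ max *z*(TM Cα) — the toggle-switch
     tryptophan floors the pocket, the most extracellular TM residues cap
     it;
  2. (*x*, *y*) lies inside the polygon through the TM helix centers at that
     grid z level (centers = mean Cα position in a ±2 Å z window, nearest
     Cα beyond the helix ends), connected in bundle order TM1→…→TM7→TM1;
  3. no heavy receptor atom is within (van der Waals radius + probe radius).

  Then *V* = *n*<sub>retained</sub> · *s*³. A Monte-Carlo rejection-sampling
  oracle with identical predicates validates the grid.

* **State comparison.** Per-residue Cα displacements after Kabsch
  superposition, helix-axis tilt angles (principal axis, unsigned acute
  angle), χ1 rotamer classes (gauche−/gauche+/trans), distance-cutoff
  contacts (polar / van der Waals / salt bridge / π–cation), and peptide
  insertion depth below the pocket's upper boundary.

* **Synthetic ground truth.** An idealized 7-helix bundle generator with
  analytic polygon areas, prism volumes and exactly known perturbations, so
  the whole pipeline is testable without downloading anything.

## Worked example

```r
library(pocketframe)

b <- make_bundle(bundle_spec())        # idealized 7TM bundle, 12 A radius
cv <- compute_cavity_volume(b$structure, b$tm, b$bw,
                            grid_config(spacing = 0.5))
cv
#> <cavity_result> 5454.8 A^3 (43638 grid points at 0.50 A spacing, probe 0.00 A)
#> <pocket_bounds> z in [-2.25, 15.75] A (height 18.00 A)

# an "activated" state: extracellular tips of TM3/4/6/7 pushed 2.2 A outward
act <- perturb_bundle(b, displace = data.frame(
  helix_id = c(3, 4, 6, 7),
  dx = 2.2 * cos(2 * pi * (c(3, 4, 6, 7) - 1) / 7),
  dy = 2.2 * sin(2 * pi * (c(3, 4, 6, 7) - 1) / 7),
  dz = 0, mode = "tip"))
cv2 <- compute_cavity_volume(act$structure, act$tm, act$bw, grid_config(0.5))
cv2$volume
#> [1] 6542.875          # the pocket expands by ~20%

cmp <- compare_states(b$structure, act$structure, b$tm,
                      align = b$tm[!b$tm$helix_id %in% c(3, 4, 6, 7), ])
cmp
#> <state_comparison> 154 residues, max displacement 2.20 A
#> helix tilts (deg): TM1 0.0, TM2 0.0, TM3 4.1, TM4 4.1, TM5 0.0, TM6 4.1, TM7 4.1
#> 0 chi1 class change(s)
```

The cavity volume is the count of retained 0.5 Å grid points times 0.125 Å³;
the bounds line shows the toggle-residue floor (z = −2.25 Å) and the TM-top
cap (z = 15.75 Å). After tipping four helices outward, the recovered maximum
Cα displacement equals the applied 2.2 Å and each tipped helix axis tilts by
~4°, as a linear tip-ramp over a 31.5 Å helix implies.

For real structures the same call chain is:
`read_structure()` → `load_annotations()` → `membrane_align()` (against any
membrane-aligned reference, e.g. from the OPM database) →
`compute_cavity_volume(..., exclude = atom_select(chain = ...))` to strip
ligand/peptide/G-protein chains. A command-line wrapper is installed at
`system.file("exec", "pocketframe", package = "pocketframe")` with
`volume`, `compare` and `synth` subcommands.

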