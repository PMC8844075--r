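---
title: "Grid-based pocket volumes and activation geometry for TM bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based pocket volumes and activation geometry for TM bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketframe)
```

## The problem

Class A G protein-coupled receptors bind their ligands in a cavity enclosed
by the seven transmembrane (TM) helices. When an agonist activates the
receptor, the extracellular helix tips move apart, the binding cavity
expands, sidechains repack (visible as chi1 rotamer changes), and the
cytoplasmic face opens to receive the Galpha C-terminal alpha5 helix.
`pocketframe` quantifies these effects from atomic coordinates: it computes
a solvent-accessible ligand-binding cavity volume bounded by the TM bundle
itself, and a set of activation-geometry measurements between paired
receptor states.

## The cavity-volume model

The receptor must first sit in the membrane frame: z is the membrane normal
and the extracellular side has larger z (the OPM convention).
`membrane_align()` superposes the receptor onto any user-supplied
pre-aligned reference by Kabsch superposition of Calpha atoms shared by
`(chain, residue)`; when a TM annotation is available, pairing is restricted
to TM residues because loops differ between states. The package does not
bundle reference coordinates; any membrane-aligned structure of a homologous
receptor works, and structures downloaded from the OPM database are already
aligned.

A regular 3D grid then covers the receptor bounding box. A grid point
belongs to the cavity when it passes three tests:

1. **Vertical bounds.** Its z lies between the Calpha z of the toggle-switch
   tryptophan at generic (Ballesteros–Weinstein) position 6.48 (the lower
   boundary: the conserved "floor" of the orthosteric pocket) and the
   largest Calpha z over all TM-annotated residues (the upper boundary: the
   TM residues closest to the extracellular surface). Both bounds use Calpha
   atoms, and the interval is closed.
2. **Lateral polygon.** At each discrete grid z level, the center of each TM
   helix is the mean (x, y) of its Calpha atoms within a +/-2 Å z window;
   where the level lies beyond a helix end, the nearest Calpha in z is used
   instead (ties break to the lower residue number). Connecting the centers
   in bundle order TM1 -> ... -> TM7 -> TM1 closes a ring: the point must
   fall inside that ring (even–odd ray casting; points on an edge count as
   inside; rings may be non-convex and are never convexified).
3. **No atomic clash.** No heavy atom of the receptor selection lies within
   (Bondi van der Waals radius + probe radius) of the point.

The volume is exactly `n_retained * spacing^3`.

### Parameters that matter

* `spacing` (Å, default 0.5). The slab thickness of the lateral boundary is
  tied to the grid spacing, since helix centers are defined per grid z
  level. A convergence check in the test suite shows 0.5 Å agrees with
  0.25 Å within 5% on synthetic bundles; 0.25 Å is used where analytic
  accuracy is asserted.
* `probe_radius` (Å, default 0). With 0 the clash rule is a bare van der
  Waals exclusion; 1.4 Å approximates a water probe. The default keeps the
  clash test minimal; the probe is exposed because the quantity of interest
  is a solvent-accessible volume and users may prefer the water-probe
  convention. Volumes are non-increasing in the probe radius.
* `window` (Å, default 2.0). The helix-center z half-window. A +/-2 Å
  window holds 2–3 of the ~3.6 residues of a helical turn, so the plain mean
  wobbles around the true helix axis by up to ~0.65 of the Calpha helix
  radius (~1.5 Å); the wobble is phase-random and averages out of the
  integrated volume. A window of 2.7 Å (a full turn) tightens individual
  centers at the cost of blurring tilted helices.
* **Receptor-only selection.** Ligands, peptide agonists, G proteins,
  antibody fragments, waters and ions must be excluded via the `exclude`
  selector before the clash test — otherwise a bound agonist self-occludes
  the pocket it opened. The comparison of interest is between receptor
  conformations, not between occupied volumes.

### Numerical choices

The grid origin is snapped to multiples of the spacing below the bounding
box, so results are deterministic for a given input and invariant to how the
file was produced. Points exactly on the bounding planes or on a polygon
edge count as inside; with both z bounds on grid levels this counts both
boundary slabs, a deliberate closed-interval convention whose effect is
bounded by `spacing * polygon_area` and covered by the voxel-surface bound
used in the tests. Degenerate inputs fail loudly with categorized errors:
a toggle residue above the helix tops is a geometry error, a missing 6.48
mapping an annotation error, an empty receptor selection an input error.

### Validation strategy

Two independent routes check the grid method. `mc_cavity_volume()` applies
the identical three predicates to uniform random samples in the bounding box
of the boundary region, giving a volume with a binomial standard error; grid
and Monte-Carlo results agree within 3 standard errors plus a voxel-surface
bound on every seeded random bundle tested. Second, the `prism_bundle()`
preset builds line helices (Calpha radius 0) on a wide 24 Å circle, so the
enclosed region is an exact heptagonal prism: the grid volume matches
shoelace-area x height to well under 2% at 0.25 Å spacing. The wide radius
and line helices are deliberate fixture design: with finite-radius helices,
atoms necessarily straddle the boundary polygon (which passes through the
helix centers), and the clash rule carves a sliver along each vertex column
that has nothing to do with discretization error; at 24 Å the sliver is
~1% of the prism.

## Activation geometry

* `ca_displacements()` superposes state B onto state A (Kabsch on a
  configurable alignment set, by default all common TM Calpha; exclude the
  moving helix when measuring it) and reports per-residue Calpha distances.
  The "extracellular tip" of a helix is its most extracellular modeled
  residue.
* `helix_axis()` takes the largest-variance principal direction of the
  centered Calpha coordinates, signed toward increasing residue number;
  `tilt_angle()` is the unsigned acute angle `acos(|a . b|)`, symmetric and
  bounded by [0°, 90°].
* `chi1_rotamer()` computes the N–CA–CB–gamma dihedral (IUPAC sign, cis =
  0°, checked against independent implementations) and classes it by the
  nearest canonical well: trans 180° +/- 60°, gauche+ -60° +/- 60°, gauche-
  +60° +/- 60°. Gly/Ala and residues with missing atoms are `undefined`
  with a warning, never an error, so a scan over a whole receptor survives
  incomplete sidechains.
* `detect_contacts()` uses distance-only criteria (polar N/O/S pairs
  <= 3.5 Å, any heavy pair <= 4.0 Å, sidechain salt bridges <= 4.0 Å,
  pi–cation <= 6.0 Å to the aromatic ring centroid). Deposited models lack
  hydrogens, so no angular hydrogen-bond term is attempted; this is a
  documented limitation, not an option.
* `insertion_depth()` measures from the pocket's upper boundary (taken as
  the top surface of the membrane) down to the deepest peptide heavy atom,
  clamped at zero. Tying the depth reference to `z_upper` is a design
  choice; the alternative (a lipid-phosphate plane) needs a membrane model
  the coordinates do not carry.

## What the synthetic generator emulates — and what it does not

`make_bundle()` places ideal alpha-helices (1.5 Å rise, 100° twist, 2.3 Å
Calpha radius — textbook constants, all overridable) at equal angles on a
12 Å circle with alternating direction, annotates them, labels the designated
toggle residue "6.48" (on helix 6, at z ~ -2 Å against helix tops at ~+16 Å,
mimicking the mid-membrane toggle below an extracellular pocket), and
optionally inserts a peptide probe to a stated depth. Every quantity in its
`GroundTruth` — axis polygon, shoelace area, bounds, prism volume, applied
perturbations — is computed analytically, independent of the pipeline under
test. `perturb_bundle()` creates paired states with exactly known tip
displacements, helix tilts and chi1 reassignments.

These bundles have no loops, no sequence, no sidechain packing, no bends or
kinks (notably no proline kink in TM6), and perfectly cylindrical helices.
Passing the synthetic tests therefore demonstrates the correctness of the
geometry and counting machinery under known conditions — not that any
particular biological number is reproduced. Reproducing published volumes
additionally depends on the deposited coordinates, the TM range table and
the membrane alignment the user supplies; the acceptance tests that consume
deposited models document exactly which files to provide.

## Problem sizes

The shipped tests and the acceptance script run on: the default 12 Å bundle
(7 x 22 residues, ~770 atoms) at 0.5 Å spacing (~4 x 10^4 retained points),
the 24 Å prism at 0.25 Å (~1.8 x 10^6 points), Monte-Carlo checks with
2 x 10^5 samples per bundle, and 3–5 randomized bundles per sweep. These
sizes were chosen so each validation route resolves its expected effect an
order of magnitude below the asserted tolerance.

## Known limitations

* The lateral boundary is a polygon through helix centers; it ignores
  sidechain-lined sub-pockets outside that ring and does not trace channels
  or tunnels (alpha-sphere or surface-mesh methods do that job).
* Helix centers from a +/-2 Å window wobble on strongly bent helices; the
  nearest-point fallback keeps the boundary defined but flattens it beyond
  the helix ends.
* The upper bound uses the global maximum Calpha z over TM residues; if one
  helix extends far above the others, the uppermost slabs are bounded by a
  polygon built mostly from nearest-point fallbacks. Per-helix alternatives
  exist but are not implemented, to keep the boundary definition single and
  predictable.
* Contact detection is distance-only and reports geometric candidates, not
  energetically validated interactions.
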