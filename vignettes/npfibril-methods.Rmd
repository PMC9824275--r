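---
title: "Model and methods behind npfibril"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind npfibril}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

npfibril is a desk-scale modelling kit for the encounter between a plastic
nanoparticle (NP) and an amyloid-beta (1-42) fibril. It builds
coarse-grained NP and fibril models, generates toy stochastic binding
trajectories, and provides the analysis operators (contact counting,
residue profiles, side/frontal classification, shape factor) used to
characterise such encounters. This vignette records the model choices,
the units and the numerical decisions, and states plainly what the toy
generator does and does not emulate.

## Units

Internal units are nanometres, Dalton, elementary charges and a reduced
energy (the short-range well depth is the energy unit; temperatures are
expressed in the same unit). Trajectory times are *pseudo-ns*: frame
labels with no claimed mapping to physical time. Files cross the unit
boundary only at I/O: GRO is nm-native, PDB and XYZ are written and read
in Angstrom.

## Coarse-grained polymer models

Three materials are supported, with different mapping resolutions:

* **Polystyrene (PS)** - 4 beads per monomer: one backbone bead `B`
  (72 Da, the vinyl unit) and a 3-bead phenyl ring `R1`-`R3` (45 Da
  each, closed into a cycle). A chain of *n* monomers has 4*n* beads and
  5*n* - 1 bonds (backbone bond, backbone-ring anchor and the ring
  cycle).
* **Polyethylene (PE)** - 1 bead per *two* monomers (72 Da); odd monomer
  counts are rounded down with a warning.
* **Polypropylene (PP)** - 1 bead per monomer (45 Da).

Chemical masses use the monomer molecular weights 104.15 (PS), 28.05
(PE) and 42.08 (PP) Da; `chemical_mass()` reports both the chemical and
the CG bead-sum mass, because mapped bead masses are not meant to
reproduce the chemical mass exactly.

Charges are assigned on a *monomer* basis: `assign_charges(x, density,
sign)` charges `round(density * n_monomers)` carriers with one
elementary charge each, on backbone beads, either uniformly or
preferring the outer shell (`placement = "surface"`). The density is a
fraction of monomers, not of beads - for PS the two bases differ by a
factor of four, so this choice is load-bearing for any charge
bookkeeping.

## Nanoparticle assembly

`replicate_chains()` packs rigid random-rotated copies of one chain into
a box without clashes; `assemble_nanoparticle()` collapses them into a
globule with a three-stage overdamped Langevin protocol: a compression
stage with a harmonic radial confinement, a cohesion stage in which a
short-range attraction (Lennard-Jones-like, well depth `eps`) pulls the
melt together, and a zero-temperature unconfined relaxation. Bonds are
harmonic; like charges interact through a screened Coulomb term whose
prefactor (`coulomb_k = 56` reduced energy x nm / e^2) is the vacuum
Coulomb constant expressed in thermal-energy units at 300 K, so that two
unit charges 1 nm apart repel with ~56 kT - deliberately un-screened by
any solvent dielectric so that surface charging has a visible
morphological effect at desk scale. The emergent behaviour, asserted in
the test suite rather than programmed in: neutral chains collapse into a
single cluster, and strongly like-charged chains fragment into several
(`n_clusters` via single-linkage clustering at the contact cutoff).

`estimate_diameter()` reports twice the mean bead distance from the
centroid plus a bead diameter, and the maximum bead-bead extent;
`shape_factor()` (below) quantifies how round the result is.

## The fibril model

The fibril is one bead per residue (42 beads per chain) built from a
two-strand beta-arch cross-section: residues 1-20 form one in-plane
strand, 21-22 the turn, 23-42 the strand packed against it. Two
protofilaments are related by a two-fold rotation *through their
C-terminal strands*, which leaves the KLVFF stretch (residues 16-20) of
both protofilaments surface-exposed on the lateral faces - the geometry
that makes targeted-binding tests meaningful. Four layers stacked with a
0.48 nm rise and 0.35 nm in-plane bead spacing form the 8-chain base
unit; `replicate_unit()` stacks it longitudinally (4 repeats give the
32-chain fibril used in the full study).

Annotation is per residue: class (`hydrophobic`, `polar`, `charged`),
charge (Asp/Glu -1, Lys/Arg +1; net -3 e per chain from 6 acidic and 3
basic residues at neutral pH, termini not charged), and face:
`define_faces()` labels residues in the terminal `depth` layers
`"frontal"` and everything else `"side"`. A base unit can also be loaded
from a PDB/GRO file (`load_base_unit()`); GRO has no chain field, so
chains are inferred from residue-number restarts.

## The toy binding simulator

`simulate_toy_trajectory()` propagates the NP as a *rigid body*
(translation + rotation, overdamped Langevin) in the field of the fixed
fibril, with minimum-image periodic boundaries. Forces are short-range
attractions with per-residue well depths from `interaction_matrix()`
(keyed by residue class, overridable per residue, e.g. `K16 = 3`) plus
screened Coulomb between NP bead charges and residue charges.

This is artifact plumbing, and the design intent matters:

* **What it emulates.** The generator can be *steered* to known binding
  behaviour - approach to a chosen face, preferential binding at chosen
  residues, or electrostatic non-binding - so that the analysis
  operators can be tested against constructed truth. The acceptance
  suite runs exactly such batteries.
* **What it does not emulate.** No solvent, no fibril flexibility, no NP
  deformation during binding, no physical time scale, no free-energy
  realism. Conclusions about real NP-fibril chemistry should come from
  the analysis of real trajectories, which the same operators accept via
  `read_trajectory()`.

Numerical choices: the deterministic drift per step is capped (0.1 nm
translation, 0.2 rad rotation) for stability near the steep core of the
potential; the thermal noise is *never* clipped, so free diffusion
remains exact. The default friction `gamma_t = 1` is deliberately small:
it compresses the slow diffusive encounter (microseconds in solvent)
onto short pseudo-ns trajectories so binding is observable at desk
scale.

## Contact analysis

A fibril residue is **in contact** in a frame when the minimum
bead-centre distance (minimum image) between any of its beads and any NP
bead is at or below the cutoff, 0.8 nm by default. The boundary is
closed - a pair exactly at the cutoff counts - and is evaluated at the
squared-distance level so no square root blurs the edge. "Number of
contacts" counts *residues in contact*, never bead pairs.

The kernel is a C++ cell list over the periodic box, with a brute-force
path for boxes smaller than four cutoffs per side. Both paths first wrap
coordinates into the box and then apply identical minimum-image
arithmetic, so they are bitwise interchangeable; the test suite asserts
`expect_identical` between them on randomized frames.

Derived statistics: per-frame class-resolved counts
(`contact_timeseries()`), time of first sustained contact
(`first_contact_time()`, with a persistence filter), per-position
contact frequency (`residue_contact_frequency()`), and the
side/frontal/none label (`classify_contact_type()`: pool all contact
events from the first contact frame on; "frontal" when the fraction of
events on frontal-face residues exceeds 0.5, ties to side).

## The shape factor

For principal moments of inertia `Ix <= Iy <= Iz` about the centre of
mass (point masses, lowest-moment axis aligned to x),

    SF = 1 - Ix / ((Iy + Iz) / 2)

SF is 0 for a perfectly round particle and exactly 1 for collinear
beads (`Ix = 0`). A uniform 2:1:1 ellipsoid scores 0.6, a useful
landmark: values near 0 mean the NP stayed globular, values toward 1
mean it elongated. `shape_timeseries()` evaluates it per frame for the
NP beads of a trajectory.

## Reproducibility

Every stochastic stage takes an explicit seed, and composite pipelines
derive per-stage seeds deterministically from one master seed. The CLI
(`npfibril_cli()`, wrapped by `exec/npfibril`) is pure with respect to
(inputs, config, seed): the same triple produces byte-identical outputs.
`export_report()` writes byte-stable CSV/JSON including the resolved
configuration and its hash.

## Limitations and open questions

* The fibril cross-section is a stylised beta-arch, not an experimental
  structure; only its topology (KLVFF exposure, C-terminal interface,
  cross-beta stacking) is asserted, not atomic accuracy.
* Charge placement operates on CG beads as full +/-1 carriers; partial
  charges and counterions are out of scope.
* The side/frontal classifier uses a fixed face-depth and threshold;
  both are configurable, and the defaults are conventions, not derived
  quantities.
* The assembly and binding simulators share LJ-like functional forms but
  separate parameter sets; no claim is made that they are mutually
  consistent thermodynamically.
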