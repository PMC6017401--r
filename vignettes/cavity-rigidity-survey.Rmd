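---
title: "Surveying protein cavity rigidity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying protein cavity rigidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CavityRigidity)
```

# The problem

Protein cavities do their work — ligand binding, catalysis,
protein–protein recognition — with a combination of shape and motion.
Geometric cavity properties are directly computable from coordinates;
mechanical rigidity is not, but it can be derived combinatorially from
the pattern of bonds and contacts, at a cost of seconds per chain
rather than the hours of an energy-based simulation. This package
implements that derivation end to end: mechanical-model construction,
rigid-cluster decomposition, volumetric cavity detection, conservation
scoring, and the joined survey metrics, together with synthetic-data
generators that make every stage testable against known ground truth.

# The mechanical model

Atoms are nodes of a bond network built from three detectors.

*Covalent bonds* connect atoms whose distance is at most the sum of
their single-bond covalent radii plus a tolerance (default 0.4 Å).
Bonds are **locked** (their atoms are merged into one rigid body) when
they have no rotational freedom: the peptide C–N bond (the omega
dihedral is planar), the carbonyl C=O, sp2/resonant side-chain bonds
taken from a 20-amino-acid template (aromatic rings, guanidinium,
carboxylate, amide), and bonds to hydrogen (a terminal atom on the
rotation axis has no independent motion to model). Everything else —
phi, psi, side-chain single bonds — is **rotatable** and becomes a
*hinge*: exactly five bars between the two bodies holding its endpoint
atoms, which leaves the one dihedral rotation free. Both endpoint
atoms are recorded as members of both bodies, so hinge atoms can later
appear in two rigid clusters.

*Hydrogen bonds* use a purely geometric criterion: donor–acceptor
distance ≤ 3.5 Å and, when an explicit hydrogen is present, a D–H–A
angle ≥ 120°; structures without hydrogens fall back to the distance
test alone, with every N/O a potential donor. Pairs closer than three
covalent bonds are excluded. We chose geometry over an energy function
(e.g. the Mayo potential used by some rigidity servers) because it is
deterministic, configurable, and has no hidden parameterisation; the
bar count per hydrogen bond (default 5) and all cutoffs are exposed in
`surveyConfig()`, so users who want a different convention can set it.

*Hydrophobic contacts* join carbon/sulfur atoms of different residues
whose van der Waals surfaces approach within 0.25 Å, deduplicated to
the closest pair per residue pair and excluded within three covalent
bonds (otherwise every backbone neighbour qualifies). They contribute
2 bars by default, the weak-tether convention of body-bar rigidity
practice. Only the hinge = 5 bars mapping is forced by the model; the
hydrogen-bond and hydrophobic bar counts are configuration
(`bar_policy`), since different rigidity packages make different
choices here.

# The (6,6) pebble game

The multigraph of bodies and bars is analysed by the body-bar pebble
game with k = 6 pebbles per node and sparsity offset l = 6, the
standard choice for 3-dimensional rigid bodies. A bar (u, v) is
accepted as independent iff 7 pebbles can be gathered on {u, v};
accepted bars are directed and consume one pebble from their tail, and
pebble searches are depth-first reversals along directed paths. The
invariant (free pebbles) + (accepted bars) = 6·|bodies| holds after
every step, and the total free DOF is the pebble count at the end.

Two implementation choices deserve a note:

* **Determinism.** Edges are inserted in sorted (u, v) order and
  searches visit neighbours in ascending id, so the full pebble state
  is bit-stable. The decomposition itself is a matroid property and
  does not depend on insertion order; the test suite checks this
  explicitly over shuffled insertions.
* **Cluster extraction.** Rather than maintaining components online
  during insertion, we query the final pebble state: the relative DOF
  between u and v is the number of pebbles collectible on the pair
  beyond the 6 trivial ones, and two adjacent bodies belong to one
  rigid cluster iff that number is 0. For body-bar frameworks (bodies
  share all 6 DOF when mutually rigid) rigid components partition the
  bodies and are internally connected, so union-find over adjacent
  zero-DOF pairs reconstructs the full decomposition. The equivalence
  is validated against an independent numerical oracle: random generic
  body poses, the standard 12-entry body-bar rigidity-matrix rows, DOF
  from the matrix rank (maximised over repeated random placements to
  avoid accidental degeneracy), and components from equality of
  null-space body motions. Two hundred random multigraphs with up to
  8 bodies and 24 bars match exactly, in DOF and in partition.

Singleton bodies with no independent incident bars are reported as
their own clusters, so every atom belongs to at least one cluster.
Cluster ids are 0-based in the XML interchange format (`body` elements
containing `point` elements whose ids are PDB atom serials), with
stable ordering by cluster id then atom id so writes are byte-stable.

# Volumetric cavity detection

The solvent-excluded surface (SES) is the morphological closing of the
van der Waals union by the probe sphere (default 1.4 Å): dilate the
atom spheres by the probe, flood away the bulk solvent, erode by the
probe. On a voxel grid (default spacing 0.5 Å; 0.2 Å for
accuracy-critical measurements) we evaluate this as a signed field:

* the analytic atom field d(x) = min over atoms of (distance − vdW
  radius), capped at the grid margin;
* the probe-centre region P = {d ≥ probe}, whose boundary voxels seed
  an exact Euclidean distance transform (separable squared-distance
  algorithm with nearest-site tracking);
* a sub-voxel correction subtracts each seed's residual clearance
  (d − probe at the seed) from the transform, so the reconstructed
  distance-to-P refers to the smooth solvent-accessible boundary
  rather than to voxel centres. Contact surfaces then sit on the atom
  spheres to second order in the spacing.

The zero level of the resulting field is triangulated by **marching
tetrahedra**: each cube splits into six tetrahedra sharing a main
diagonal, and the linear iso-surface inside each tetrahedron
contributes one or two triangles. Marching tetrahedra gives the same
linear-interpolation accuracy as table-driven marching cubes with case
logic simple enough to verify by inspection; degenerate (zero-area)
triangles from iso-through-corner events are filtered at 1e-8 Ų.
Measured on a single sphere, the area error falls monotonically with
spacing and is below 2% at 0.2 Å. A zero probe short-circuits to the
bare vdW union field.

Pockets and voids are found with a second closing at the **envelope
probe** (default 8 Å): pocket voxels are empty voxels inside the
envelope, voids are empty voxels unreachable from the bulk solvent
(6-connected flood fill, the conservative choice that does not let
solvent slip through diagonal voxel gaps). Candidate cavities are
26-connected components of those voxels; each inherits the surface
triangles whose generating grid cube touches it (the deepest empty
corner decides ties), which yields exactly the protein-facing boundary
— pocket mouths generate no triangles because the field does not
change sign there. Two filters remove discretisation artefacts: a
component must be at least half a voxel deep, and at least `min_area`
(default 50 Ų) in surface area. Both the filtered list and the full
candidate table (attribute `"allCavities"`) are returned, because
survey conventions differ on where to cut small cavities; downstream
consumers can apply either stream.

Lining atoms are assigned per triangle as the atom nearest the
triangle centroid (the centroid is the natural single query point for
a "closest atom per triangle" rule; per-vertex voting changes the
assignment only at patch borders), and cavity residues are the lining
atoms' residues in sequence order.

# Evolutionary-trace aggregation

Per-residue real-value conservation scores are read from server-style
ranks text files (comment lines, whitespace-delimited columns;
positions configurable since the dialect varies). Scores keep their
input orientation — no rescaling. Aggregation over a residue set
reports mean, median and the scored count; unscored residues are
skipped, never zero-filled, and a fully unscored set propagates as
missing so that chains without conservation data flow through the
pipeline with ET fields empty rather than fabricated.

# Join metrics

A cavity and a rigid cluster are associated iff they share at least
one atom (threshold configurable). Per-cavity records report the
participating-cluster count, the number of lining atoms that belong to
a participating cluster, and the percentage of *all* atoms of the
participating clusters that lie in the cavity — the pooled denominator;
with one 10-atom cluster of which 8 atoms line the cavity the record
reads 80%, with two 10-atom clusters and 7 lining atoms it reads 35%.
The pooled convention was chosen because the survey quantity of
interest is how far the rigid material backing a cavity extends away
from its surface; per-cluster percentages are recoverable from the
association map. Per-cluster records report cavity participation and
the mean and maximum area of the cavities touched. Bipartite degree
conservation (Σ clusters-per-cavity = Σ cavities-per-cluster) is an
exact invariant and is tested on random fixtures.

# Survey statistics

Pearson's r is the default association measure (Spearman behind a
flag), computed after pairwise deletion of missing values with the
dropped count reported. Nonlinear least-squares fits support three
curve families — `gaussian_peak` (the default, matching the
approximately normal distribution of the percent-rigid-atoms metric),
`saturating_exponential` and `power_law` — using a deterministic
multi-start grid over data-derived starting values, with fit quality
reported as the correlation between fitted and observed responses.
Chain subsampling (the survey's 1000-chain plotting device) is uniform
without replacement over chains under an isolated, fixed seed.
`exportPlotData` projects the record tables onto the eight documented
scatter-plot axis sets.

# Synthetic data: what it does and does not show

The generators produce every input the pipeline consumes, each with
machine-checkable ground truth:

* `makePolymerChain` — ideal-geometry poly-alanine backbones (fixed
  bond lengths/angles, extended or alpha-helical) with a seeded
  fraction of rotatable bonds relabelled locked. Ideal geometry is
  deliberate: rigidity ground truth must be derivable by union-find
  over locked bonds, which Ramachandran-sampled conformers would not
  allow. The helix reproduces the i→i+4 backbone hydrogen-bond ladder
  with near-ideal geometry (N···O 3.09 Å, D–H–A 165°).
* `makeHollowShell` / `makeOpenPocket` — Fibonacci-lattice atom shells
  with an interior void or a small-mouthed pocket. Closure is
  *verified* at generation time by a voxel flood-fill leak test, so
  cavity counts are guaranteed, not assumed. The expected interior
  area is the contact sphere of the probe rolling inside,
  4π(R − r_vdW)²; nested shells must be separated by more than
  2(r_vdW + probe) or the generator refuses, because a thinner gap is
  genuinely not a cavity at the stated probe.
* `makeRandomBodyBarGraph` — uniform multigraphs for the rank-oracle
  equivalence suite.
* `makeMetricCorpus` — per-chain record tables whose key metric pairs
  are bivariate normal at a chosen latent correlation, mapped to count
  support by rounding with floor 1. Support means and spreads
  (residues 45 ± 12, clusters 40 ± 10, atoms 120 ± 30, participation
  30 ± 8) are chosen so rounding and truncation attenuate the latent
  correlation by well under 0.001, making correlation-recovery tests
  meaningful at ±0.02–0.03 tolerances; record counts per chain are
  negative-binomial (size 5, mean 10, plus one).
* `makeEtTable` — uniform rvet scores on [1, 100] with an optional
  missing fraction, written in the ranks dialect.

These fixtures exercise the algorithms, not the biology: synthetic
chains have no packed cores, no side-chain diversity, no real
hydrogen-bond networks, and the metric corpora impose a correlation
rather than deriving one from structure. Passing tests therefore
demonstrate correctness of the machinery (decomposition, detection,
measurement, joining, statistics) under known conditions — they do not
re-establish the empirical survey findings on real proteins, which
require a structure corpus and conservation data as inputs.

# Numerical choices and degenerate inputs

* Grid margins default to 10 Å so the 8 Å envelope closing has room;
  a margin smaller than the envelope probe is an error, as is a grid
  beyond `maxVoxels`.
* Alternate locations resolve to the highest-occupancy copy (ties:
  first in file); HETATM records are excluded unless requested.
* Unknown elements fall back to carbon-like radii with a warning;
  unknown residues get all-rotatable covalent bonds with a warning.
* Pebble-game ties (tail selection, search order) are fixed by
  ascending id; XML and SURF writers use fixed numeric formats, so all
  artifacts are byte-reproducible.
* Empty structures, empty meshes, comment-only ET files, zero-record
  aggregate tables and cavities with no participating cluster all have
  defined behaviour (errors or flagged records, never silent zeros).

Problem sizes in the shipped tests were chosen to keep the whole suite
in the minutes range on one core: oracle graphs ≤ 8 bodies, shells of
~450 atoms at 0.5 Å spacing, accuracy measurements on single spheres
at 0.2 Å, end-to-end runs on 60-residue chains, and 5,000-pair
correlation recoveries. All scale linearly (grid) or near-linearly
(pebble game) to survey-size inputs.

# Known limitations

* The cavity stage is a functional volumetric stand-in for
  constructive-solid-geometry surface tools: areas agree with analytic
  ground truth within the stated grid tolerances but will not match
  any particular external mesher triangle-for-triangle.
* Hydrogen-bond perception is geometric; no energy ranking or dilution
  series is implemented.
* The residue template covers the 20 standard amino acids; modified
  residues and ligands are treated as all-rotatable rather than
  parameterised.
* One chain at a time: no biological-assembly expansion, no mmCIF
  input, no inter-chain contacts.
* Cavity volume is not computed — the survey consumes areas, atoms and
  residues only.
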