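---
title: "molkit: models, contracts and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molkit: models, contracts and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molkit)
```

# The data model

Trajectory analysis code everywhere is built on three entities: a
**Topology** (the time-independent identity of every atom: name, residue,
chain, mass, charge, element, plus bonds), a **State** (one frame:
coordinates, an optional periodic box, time and step), and **Selections** —
views that point at a subset of atoms and act as the handle for every
measurement and modification. Selections hold no data: all reads and writes
go through storage shared with the owning system, so an edit made through
one selection is immediately visible through every other.

In a language with move semantics these views are guarded by the compiler.
molkit reproduces the same guarantees as *runtime contracts*: a
`MolSystem` copies its Topology and State into an internal environment
(R's reference-semantics container) when it is built, and the caller is
expected to treat the original objects as handed over. Every selection made
from a system carries the system's **access kind**, fixed at construction:

| kind              | data access | may overlap | validity check |
|-------------------|-------------|-------------|----------------|
| MutableSerial     | read/write  | yes         | no             |
| BuilderSerial     | read/write  | yes         | per access     |
| ImmutableParallel | read only   | yes         | no             |
| MutableParallel   | read/write  | **no**      | no             |

The four kinds cover the four usage patterns of analysis scripts:
single-worker read/write scripting; system building where atoms are added
and deleted; read-only frame-parallel analysis; and concurrent writes,
which are only safe when writers can never alias. The table's flags are
enforced at the operation level: `applyTransform()` on an
`ImmutableParallel` selection raises a contract error, structural edits are
methods of `BuilderSerial` systems only, and `MutableParallel` selections
are registered in a **used-index registry**.

## The used-index registry

The registry is the bookkeeping that replaces compile-time alias checking:
it always equals the union of the index sets of all live `MutableParallel`
selections on a system. Creation claims an index set after a disjointness
test (one uninterruptible step in R's evaluation model); release removes
it; releasing indices that were never claimed is an internal-consistency
error and raises rather than being ignored. Because R has no deterministic
destructors, release is explicit (`releaseSelection()`), or implicit
through fragmentation — tying it to garbage collection would make the
registry's contents timing-dependent and the exactness invariant
untestable.

## Sub-selections

Three routes create selections from selections, differing in what happens
to the parent:

* `subselect()` — narrows to the parent's atoms that also satisfy an
  expression; parent stays alive. Result is always a subset:
  `subselect(sel, e)` equals the system-wide evaluation of `e` intersected
  with the parent's index set (a test asserts exactly this oracle).
* `splitFragments()` — partitions the parent by a key (residue, chain, a
  user function); parent stays alive.
* `intoFragments()` — the same partition, but the parent is consumed
  (marked dead before any fragment is handed out). This is the only route
  open to `MutableParallel` selections: a live parent coexisting with its
  fragments would violate no-overlap. The parent's registry claim is
  exchanged for the per-fragment claims with no intermediate state in which
  a third party could claim those indices.

`BuilderSerial` selections additionally carry their birth *generation*.
Deleting atoms re-indexes the survivors and bumps the system generation, so
every pre-existing selection errors on its next access; appending preserves
all indices and deliberately does not bump it. A plain bounds check would
be insufficient — after re-indexing an in-bounds index can silently point
at the wrong atom — so staleness is the safe contract.

# Numerical methods

## Units and indexing

nm, ps and amu internally (the Gromacs convention); PDB/XYZ/DCD Angstrom
values are divided by 10 on read and multiplied on write. Atom indices are
1-based throughout the R API, as the language expects; the selection
grammar's `index` keyword is 0-based, matching molecular viewers, and file
resids are used verbatim.

## Kabsch superposition

`fitTransform()` minimizes weighted RMSD via the SVD of the weighted
covariance matrix; when the candidate rotation would be a reflection the
sign of the smallest singular vector is flipped, so the result is always a
proper rotation (det = +1), even for mirrored or near-planar inputs where
naive least squares would return det = −1. Collinear point sets have no
unique rotation and are refused. The fit is checked two ways: constructed
rigid motions must be recovered to < 1e−10 nm post-fit RMSD, and on
degenerate mirrored sets the fitted RMSD must not exceed the best of
thousands of random proper rotations.

## Periodic boxes and minimum image

Boxes are stored lower-triangular (a along +x, b in the xy-plane), volume
positive; arbitrary vectors are rotated into this canonical frame on
ingestion, giving a unique representation. Minimum-image displacements are
exact for orthorhombic cells (per-axis rounding in fractional space); for
triclinic cells the rounded image is refined over the 27 neighboring
lattice translations, which is exact for the reduced cells this package
constructs. A property test checks the result against a brute force over
the 5³ translation shell.

## Periodic center of mass

With `pbc = TRUE`, `centerOfMass()` maps each fractional coordinate to an
angle on the unit circle, takes the mass-weighted mean direction per box
axis, and maps the mean angle back into the cell. Two equal masses at
x = 0.5 and x = 9.5 in a 10 nm box thus average to x ≡ 0 (mod 10), not to
the meaningless midpoint 5. This circular-mean form was chosen over
unwrap-then-average because it needs no bond information; the caveat,
stated here deliberately, is that it is physically meaningful only for
clusters smaller than about half the box — a cluster wider than that has no
well-defined periodic center in any convention.

## Neighbor search

`searchWithin()` bins atoms into a cell grid whose cells are at least one
cutoff wide along each box height and scans the 27 neighboring cells of
every occupied query cell; triclinic grids are built in fractional space
while distances are evaluated as Cartesian minimum image. Ties at exactly
the cutoff are *included* (≤). If the cutoff exceeds half the smallest box
height — where the one-shell assumption breaks — the search falls back to
brute-force minimum image with a warning rather than silently missing
pairs. Correctness is asserted as exact set equality with an O(N²) brute
force across box types, densities, seeds and cutoffs.

## Solvent accessible surface area

`sasa()` is a numeric Shrake–Rupley quadrature: `nPoints` golden-spiral
points on each atom's probe-expanded sphere, a point counting as exposed
when outside every neighbor's expanded sphere, and per-atom area equal to
the exposed fraction times the sphere area. Van der Waals radii are Bondi
values; an element without a tabulated radius is an error, never a silent
default. The quadrature error scales like 1/nPoints; at the default 960
points the two-sphere overlap case stays within 2% of the closed-form
spherical-cap area over the full separation range (measured maximum ≈
0.5%), and an isolated atom is exact to the lattice discretization
(well under 1%). Periodic images are not considered; SASA of a
boundary-straddling cluster should be computed after unwrapping.

## Jump removal

`unwrapAtoms()` re-images atoms sequentially in selection index order: each
atom is moved to the periodic image nearest the previously processed atom,
walking both directions from an anchor. Index order rather than bond
topology is used because bonds may be absent from many formats; for
branched molecules whose index order jumps spatially this rule can
misplace branches — a documented limitation, not a silent one.

# File formats

PDB reading is a fixed-column parse of ATOM/HETATM (with CRYST1 becoming
the box and the first MODEL of a multi-model file used for structures);
blank name fields become `"X"`, elements fall back to inference from atom
names (with monoatomic-ion residues recognized so `CA` in a protein is
carbon but the ion `CA` is calcium), and masses come from a bundled element
table because the format has none. Writing renumbers serials from 1 and
preserves resids verbatim. DCD is the CHARMM dialect: 84-byte `CORD`
header, optional per-frame unit-cell record (lengths in Angstrom, angles in
degrees, cosine-form values recognized on read), float32 coordinates, byte
order auto-detected from the leading record marker, fixed-atom files
refused. Frames are addressed by absolute byte offset, so `readFrame(i)`
is O(1) in any order — the random-access contract that jump removal and
frame-parallel drivers rely on. An XTC adapter seam exists in the reader
class hierarchy but no codec is bundled; GRO/TPR/mmCIF are out of scope.

# Frame-parallel execution

`analyzeTrajectory()` deals frames round-robin to forked workers. Each
worker receives its own system replica (private coordinate buffer) and
reopens its own file handle, so no two workers ever share a mutable State
or a seek position; results are reassembled in frame order, making the
output provably independent of worker count — the suite asserts bytewise
CSV equality for 1, 2 and 4 workers. Serial-kind tasks are rejected for
multi-worker runs up front, mirroring the rule that serial selections never
leave the worker that created them. `processFragments()` is the
within-frame counterpart: it fragments a `MutableParallel` selection
(consuming it) and lets workers edit disjoint fragments of the *same*
state, with registry disjointness making the merge of their writes
well-defined.

The scheduler itself is deliberately unspecified beyond these contracts; a
worker pool over frame chunks with caller-side reduction is the simplest
implementation that satisfies them.

# The synthetic fixture generator

`generateSystem()` builds chains of residues along self-avoiding random
walks: one 0.38 nm step per residue (the CA–CA distance in real proteins),
a 0.25 nm clash tolerance between residue centers with bounded retries
(raising "box too small" on failure), and N/CA/C/O plus carbon dummies
jittered around each walk position. "Protein-like" here means realistic
*field values* — names, resids, chains, elements, masses, densities —
not realistic stereochemistry: none of the operations under test depend on
dihedral plausibility, only on plausible particle geometry and identity.
Passing tests therefore demonstrate correctness of selection algebra,
geometry, I/O and scheduling on data of realistic shape and size; they say
nothing about force-field-level realism, and are not meant to.

`generateTrajectory()` writes frame 1 exactly equal to the input state and,
in rigid mode, applies a fresh random rotation (up to 0.3 rad) and
translation (up to 0.3 nm per axis) about the system center for each later
frame, recording every transform in a JSON manifest. That manifest is
ground truth: superposition must recover each stored rotation from the
frames alone, and the align+RMSD task must report ≈ 0 (bounded by float32
storage, < 1e−5 nm) on such a trajectory. Brownian mode adds cumulative
Gaussian steps (σ = 0.02 nm per frame by default); mixed mode combines
both and is used where a determinism check needs non-trivial frames. All
generators take integer seeds and restore the caller's RNG state.

Scale of the bundled checks: the worker-count-independence suite runs the
three tasks on a 4,320-atom, 100-frame system (two 270-residue chains of
8-atom residues in a 7.5 nm box) — the in-repo analog of a small
production system — while correctness oracles run at 1,000 atoms and
below, where brute-force references are exact and fast.

# Design choices made here

* **Empty selections are errors.** A silently empty selection hides
  analysis bugs; `trySelectAtoms()` exists for deliberate probing.
* **`within` includes the reference atoms** in its result by default
  (flag-controlled), so "within 1 nm of residue 5" means the neighborhood
  including residue 5 itself.
* **The selection grammar is this package's own** (`all`, `name`,
  `resname`, `resid`, `chain`, `index`, `within r of (...)`, boolean
  operators): a minimal VMD-like language sufficient for the three
  benchmark tasks, not a reimplementation of any particular tool's syntax.
* **The RMSD task fits on one selection and measures on another**
  (defaulting to the same), with a mass-weighted fit by default — the
  `gmx rms` convention.
* **CSV reproducibility headers** carry the package version and task
  parameters but no timestamps or worker counts, because worker-count
  independence is asserted bytewise.

# Known limitations

Velocities and forces are carried through containers but never computed
with, and are not written to any format. DCD holds cell lengths and angles
only, so a triclinic box survives a DCD round trip up to its canonical
lower-triangular form. Text trajectory readers (XYZ, multi-model PDB) keep
the file's lines in memory; DCD is the format intended for large frame
counts. SASA ignores periodic images. The circular-mean periodic center of
mass degrades for clusters comparable to the box size. Bond-graph
connectivity splitting is not provided — fragment keys are residue, chain,
name or user functions.
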