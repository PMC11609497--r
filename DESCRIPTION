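Package: molkit
Title: Memory-Contract Selections and Frame-Parallel Analysis of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for analysis of molecular dynamics trajectories built
    around a Topology/State/Selection data model with explicit access-kind
    contracts. Selections are kind-tagged live views over shared atomic data:
    serial kinds for single-worker scripting and system building, parallel
    kinds for frame-parallel analysis with a used-index registry that
    guarantees mutable parallel selections never overlap. Includes readers
    and writers for PDB, XYZ and CHARMM-style DCD files with random frame
    access, a VMD-like selection expression language, Kabsch superposition
    and RMSD, periodic-boundary-aware centers of mass, cell-list neighbor
    search for distance-based selections, Shrake-Rupley solvent accessible
    surface area, a deterministic synthetic-system generator with ground-truth
    rigid motions, and a frame-parallel driver exposing the three canonical
    trajectory tasks (align+RMSD, within-distance center of mass, selection
    extraction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'molkit-package.R'
    'elements.R'
    'box.R'
    'topology-state.R'
    'system.R'
    'selection-grammar.R'
    'neighbor.R'
    'selection.R'
    'measure.R'
    'sasa.R'
    'modify.R'
    'io-structure.R'
    'io-trajectory.R'
    'synth.R'
    'parallel.R'
    'tasks.R'
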