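Package: cglearn
Title: Differentiable Coarse-Grained Molecular Simulation for Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained (four beads per residue) molecular simulation
    engine for proteins in which every parameter of a binned, knowledge-free
    force field can be learned by backpropagating a structural loss through
    the integrator. Provides structure input/output (PDB, PSIPRED ss2, an
    internal peptide builder), the binned potential model with its full
    indexing scheme, velocity Verlet dynamics with an optional Andersen
    thermostat, reverse-mode (adjoint) gradients of a Kabsch-RMSD loss with
    respect to all potential parameters, a training loop with step-count
    curriculum and Adam optimiser, and downstream protocols: folding runs,
    per-residue flexibility (RMSF), helix-fraction analysis, sequence
    threading, fixed-backbone design and decoy scoring.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
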