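---
title: "Differentiable coarse-grained simulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable coarse-grained simulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cglearn)
```

## The model

cglearn simulates proteins at a resolution of four point particles per
residue: the backbone nitrogen (N), the alpha carbon (CA), the carbonyl
carbon (C), and the unweighted centroid of the heavy sidechain atoms (SC).
There is no explicit solvent, no periodic box and no neighbour list; every
bead interacts with every other bead. Masses are unitless model masses:
15 for N (the amide hydrogen is folded in), 13 for CA, 28 for C (carbonyl
oxygen folded in), and the summed heavy-atom mass of the sidechain for SC.
Glycine, which has no heavy sidechain atoms, receives a pseudo-C-beta bead
placed 1.53 Å from CA along the tetrahedral direction and an artificially
heavy mass of 10 so that its bead does not dominate the time-step
requirement. Because the model is coarse-grained, energies, temperatures
and times carry no physical units; only their ratios matter.

The potential is a set of 29,360 independent lookup tables, each holding
energy values on 140 evenly spaced bins:

* **Pairwise distances** (28,960 tables). Every unordered pair of the 80
  atom types (4 beads × 20 amino acids) has a *general* table (3,240
  tables, bins on 1–15 Å) used for residue separations greater than 4.
  Ordered type pairs at separations 1–4 get their own *close-residue*
  tables (4 × 6,400, bins on 0.7–14.7 Å), which let the model learn local
  constraints — including the C–N peptide bond at separation 1 —
  separately from packing preferences. Atom pairs within one residue use
  *same-residue* tables (6 bead pairs × 20 amino acids = 120, bins on
  0.7–5.6 Å); covalent bonds are represented implicitly by these tables.
* **Bond angles** (100 tables, bins on 60–180°). Five angles per residue:
  N–CA–C, CA–C–N(+1), C(−1)–N–CA, and the two sidechain angles N–CA–SC
  and C–CA–SC, per amino acid.
* **Torsions** (300 tables, bins on −180–180° plus two pad values). Five
  torsions per residue — phi, psi, omega and the two sidechain torsions
  C(−1)–N–CA–SC and SC–CA–C–N(+1) — per amino acid and per predicted
  secondary-structure state (H/E/C), so helical and strand residues can
  acquire different backbone preferences. The two extra pad values per
  table are independent learnable parameters read by the force rule
  across the ±180° seam, which makes the derived force periodic.

The total parameter count is 28,960·140 + 100·140 + 300·142 = 4,111,000.
All values start at zero: the initial potential is flat, exerts no force,
and everything the force field knows is acquired during training.

The five-angle and five-torsion atom assignments above fully constrain
the SC bead relative to the backbone; each term is attributed to the
amino acid (and, for torsions, secondary-structure state) of the residue
owning the CA pivot, and terms referencing a nonexistent terminal
neighbour are simply omitted.

## Forces from binned tables

At each step, for every interaction term the current value of its
geometric property (distance, angle or torsion) is computed and assigned
to the bin whose centre is nearest — equivalently the bin whose interval
contains the value, with values on a bin edge resolving to the higher bin.
For non-periodic tables the first and last bins are excluded: values
beyond the range occupy the penultimate (or second) bin, so out-of-range
geometry still feels a restoring force. The force magnitude is the
central finite difference across the occupied bin b:

F = ½ (E(b−1) − E(b+1)),

which is positive when energy decreases with increasing property value.
The force on each participating bead is F times the analytic gradient of
the property with respect to that bead's position (distance gradients are
unit vectors; angle and dihedral gradients are the standard perpendicular
directions scaled by the inverse bond lengths, with inner-atom terms
fixed by the chain rule). Because each property is invariant under rigid
motion, every term contributes exactly zero net force and zero net torque;
the test suite verifies both to 10⁻⁹. This gradient-direction convention
is the only one consistent with momentum and angular-momentum
conservation; applying the same magnitude along unnormalised directions
would leak torque. Under it, a table whose energy descends with distance
is repulsive — beads move outward, down the energy gradient.

## Integration and thermostat

Velocity Verlet advances the system: x(t+Δt) = x(t) + v(t)Δt + ½a(t)Δt²,
new accelerations from the tables, then
v(t+Δt) = v(t) + ½(a(t)+a(t+Δt))Δt. Training simulations run in the NVE
ensemble (no thermostat) with Δt = 0.02. Production runs use Δt = 0.004
and the Andersen thermostat: after each velocity update, every bead
independently suffers a collision with probability Δt divided by a
coupling constant (default 25), and a colliding bead has all three
velocity components redrawn iid from Normal(0, temperature) with
temperature 0.015 by default. Collisions are per-bead (all components
redraw together) — redrawing components of different beads independently
would give the same marginal statistics but is not what a physical
collision does. The thermostat is applied after the Verlet velocity
update. A divergence guard aborts any run whose coordinates exceed 10⁴ Å
with an error recommending a smaller time step, converting silent
blow-ups into diagnosable failures.

## Differentiating through the simulation

The training signal is the loss log(1 + R_f), where R_f is the all-bead
RMSD (Kabsch superposition, proper rotations only) between the final
simulated conformation and the native structure. The gradient of this
loss with respect to every table value is computed by reverse-mode
differentiation through the integrator: the forward pass stores the
coordinate history, and an adjoint pass runs the update equations
backwards, carrying cotangents of positions, velocities and
accelerations.

Two design choices keep this exact and fast:

* **Frozen discretisation.** Bin selection and clamping are treated as
  constants of the backward pass; gradients flow only through the energy
  values entering the force rule (each with coefficient ±½). The loss as
  a function of the parameters is therefore piecewise smooth, and the
  backward pass differentiates the smooth piece the forward pass ran on.
* **Complex-step Hessian products.** The adjoint pass needs, per step,
  the product of the force-field Jacobian with a cotangent vector. With
  bins frozen the force field is the gradient of a scalar, its Jacobian
  is symmetric, and the product equals a directional derivative — which
  is evaluated as Im f(x + ih·w)/h with h = 10⁻²⁰. The property-gradient
  formulas use only arithmetic and square roots, so they are
  complex-analytic and the directional derivative is exact to machine
  precision (unlike a finite difference, there is no subtractive
  cancellation). One complex evaluation per backward step supplies both
  the coordinate adjoint and the per-term dot products feeding the table
  gradients.

The package's gradient contract — checked in the test suite and
recomputed by `scripts/acceptance.R` — is that the adjoint gradient
matches central finite differences (perturbation 10⁻³) to a relative
error of 10⁻³ for ≥50 randomly sampled parameters on a 3-residue,
20-step simulation; the observed agreement is typically 10⁻⁷ or better.
The gradient of the Kabsch RMSD itself holds the optimal rotation fixed
(envelope theorem), which is exact at the optimum and verified against
finite differences.

Memory scales linearly in step count (the coordinate history), which is
the usual cost of reverse-mode differentiation through time; production
simulation uses constant memory because no tape is kept.

## Training protocol

One epoch simulates every protein once, in a seeded random order, from
its native coordinates with starting velocities drawn from
Normal(0, 0.1). Loss gradients are accumulated over a configurable number
of proteins (the reference protocol uses 100; the mean gradient is
applied), then one Adam update (learning rate 10⁻⁴, standard β₁ = 0.9,
β₂ = 0.999, ε = 10⁻⁸) modifies the tables. At epoch 38 the optimiser
state is discarded and re-created with learning rate 5×10⁻⁵. Simulation
length follows a curriculum: 250 steps in epoch 1, increasing by 250
every 5 epochs to a cap of 2,000 from epoch 36 — short early simulations
let the model first learn local chemistry (covalent distances, clashes)
before confronting slower degrees of freedom. Simulations that diverge
are skipped and logged rather than aborting the epoch. All stochasticity
(velocity draws, epoch shuffling) derives from one master seed through
fixed arithmetic, so runs are exactly repeatable; a fresh velocity draw
is made for every simulation of every epoch.

### Scaled-down training protocol

The reference protocol (2,004 proteins, 45 epochs, GPU-months) is far
beyond a desk run, so the package's self-check trains on five synthetic
mini-proteins (6–12 residues, helix/strand/coil/mixed topologies from the
fixture generator) for 20 epochs with the curriculum capped at 300 steps.
With ~100 optimiser updates instead of ~90,000, the reference learning
rate cannot move parameters to a force-relevant scale: holding a bead
with velocity ~0.1 over ~300 steps of Δt = 0.02 needs forces of order
0.4, hence adjacent-bin energy differences of order 1, and since each
Adam update moves a parameter by at most the learning rate, ~100 updates
require a rate of order 10⁻². The scaled protocol therefore uses
accumulate = 1 (one update per protein, the batch-size-1 limit of the
reference protocol) and learning rate 0.01, chosen once from this
analysis. Under it the mean final-epoch R_f falls roughly 40% below the
epoch-1 value; the package asserts at least a 30% drop. A companion check
plants a single harmonic bond (minimum at 2.0 Å) in a one-residue system,
trains only that table through the R_f loss, and requires the learned
minimum to land within one bin of the target.

## Analysis protocols

* **Starting conformations.** Folding runs start from the conformation
  implied by predicted secondary structure: phi = −60°, psi = −60° for
  helical residues, phi = −120°, psi = 140° otherwise; omega is 180°
  everywhere. Random-coil starts draw phi uniformly from (−180°, −30°)
  and psi from (−180°, 180°).
* **Helix fraction** is the fraction of non-terminal residues with phi
  strictly inside (−120°, −30°) and psi strictly inside (−60°, 30°)
  (boundary values count as non-helical; "between" is read as the open
  interval). Trajectory traces may be smoothed over a window of five
  snapshots either side.
* **RMSF** discards a burn-in prefix, superposes every remaining snapshot
  onto the post-burn-in mean structure (the mean is estimated by aligning
  to the first retained snapshot, then refined once), and reports the
  per-residue RMS deviation of the CA bead from its mean position.
* **Threading** copies the native backbone, places each SC bead along the
  native CA→SC direction at the distance minimising the learned
  same-residue CA–SC table for the candidate amino acid, runs a brief
  (100-step) deterministic steepest-descent minimisation, and reports the
  final energy. The minimiser moves beads by 0.01 Å per unit force,
  capped at 0.1 Å per bead per step — steepest descent was chosen because
  the protocol only requires a fixed small number of relaxation steps,
  and determinism matters more than convergence rate. All beads move by
  default; a flag can freeze the backbone.
* **Fixed-backbone design** starts from a random sequence drawn from the
  PDB background composition (leucine 9.6%, tryptophan 1.2%), and for
  2,000 trials mutates one uniformly chosen position to a
  background-drawn amino acid, re-threads, and accepts if the energy
  drops; increases of 10 or more are always rejected; increases in
  between are accepted with probability falling linearly from 0.25 at the
  first trial to 0 at trial 1,000. Each trial re-threads from the native
  structure rather than the previous minimised state, matching the
  threading definition of sequence energy.
* **Decoy scoring** is the total table energy of each structure; the
  native rank and the native-to-best-decoy gap are reported, and an
  all-equal (flat-potential) ranking is flagged as degenerate rather
  than reported as rank 1.

## Synthetic data

`make_mini_protein` builds 3–30-residue peptides from idealised phi/psi
values per secondary-structure state (helix −57/−47, strand −130/135,
coil −80/130) with small seeded jitter, through the same NeRF chaining
used for starting conformations (ideal bond lengths N–CA 1.46 Å, CA–C
1.52 Å, C–N 1.33 Å; angles 111°, 116°, 122°). SC beads sit at idealised
per-amino-acid CA–SC distances along the pseudo-C-beta direction. These
fixtures have realistic local geometry and the correct bead/mass
structure, which is what the dynamics, gradient and training machinery
exercise. They are not real proteins: they lack native tertiary packing,
sequence-structure correlation beyond the ss-typical residue pools, and
any experimental noise. Tests passing on them demonstrate that the
machinery (forces, integration, gradients, optimisation, protocols) is
correct — not that the learned toy potentials transfer to real
structures, which requires training on a curated PDB set at the reference
scale.

`make_toy_potential` plants analytic forms (harmonics, explicit values)
on named tables so tests know the true minimum of what training or
scoring should recover.

## Numerical choices

* Bin tie-breaks: a value exactly on a bin edge belongs to the higher
  bin; ±180° torsions wrap to the first bin. Argmin over a table
  resolves exact ties to the higher bin.
* Energy lookup uses the clamped bin (2..139 for non-periodic tables), so
  the outer bins affect only forces near the range edges.
* Degenerate dihedrals (colinear atoms) evaluate to 0° with a flag;
  angle gradients guard the sin θ denominator at 10⁻¹² scale.
* Kabsch superposition excludes reflections through the SVD determinant
  sign rule, which also handles rank-deficient (collinear/planar) point
  sets; the RMSD gradient returns zero at exact coincidence.
* Gradient accumulation sums sparse per-simulation gradients and divides
  by the batch count (mean), so the learning-rate scale is independent of
  the accumulation setting.
* Divergence is an error, not a warning, and names the step at which the
  bound was crossed.

## Limitations

The engine is a faithful desk-scale implementation: pure R with
vectorised per-step force evaluation (~1–5 ms per step for 10–30 residue
systems). Reproducing the reference-scale results — folding 10–36-residue
proteins to 2–4 Å over 12 million thermostatted steps, Table-1-scale
design fractions, decoy discrimination on 3DRobot sets — requires the
full trained potential and orders of magnitude more compute than the
self-checks run; the protocols are implemented and tested on toy
potentials with planted structure instead. Sidechains are single
centroids, so rotamer detail beyond the CA–SC distance distribution is
out of reach, and the absence of explicit hydrogen bonding makes
beta-turn rigidity depend entirely on learned distance tables.
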