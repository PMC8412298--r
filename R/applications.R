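# Downstream protocols: flexibility analysis (RMSF), helix-fraction
# measurement, sequence threading and energy scoring, fixed-backbone
# design, decoy ranking and folding runs.

#' Per-residue C-alpha RMSF of a trajectory
#'
#' Discards the first \code{burn_in_snapshots} snapshots, superposes every
#' remaining snapshot onto the post-burn-in mean structure (Kabsch over
#' all beads; the mean is estimated by aligning to the first retained
#' snapshot and refined once) and returns the root-mean-square deviation
#' of each residue's CA bead from its mean position.
#'
#' @param trajectory a \code{cg_trajectory}.
#' @param burn_in_snapshots number of leading snapshots to discard.
#' @return numeric vector of per-residue RMSF (Angstrom).
#' @export
rmsf <- function(trajectory, burn_in_snapshots = 0L) {
  n <- dim(trajectory$coords)[1]
  keep <- seq_len(n) > burn_in_snapshots
  if (sum(keep) < 2L) {
    stop("burn-in leaves fewer than 2 snapshots")
  }
  snaps <- trajectory$coords[keep, , , drop = FALSE]
  ns <- dim(snaps)[1]
  ref <- snaps[1L, , ]
  aligned <- array(NA_real_, dim(snaps))
  for (s in seq_len(ns)) aligned[s, , ] <- kabsch_superpose(snaps[s, , ], ref)
  mref <- apply(aligned, c(2, 3), mean)
  for (s in seq_len(ns)) aligned[s, , ] <- kabsch_superpose(snaps[s, , ], mref)
  mref <- apply(aligned, c(2, 3), mean)
  r <- nchar(trajectory$sequence)
  ca <- bead_index(seq_len(r), 2L)
  vapply(ca, function(b) {
    dev <- sweep(aligned[, b, , drop = TRUE], 2, mref[b, ])
    if (is.null(dim(dev))) dev <- matrix(dev, ncol = 3L)
    sqrt(mean(rowSums(dev^2)))
  }, numeric(1))
}

#' Alpha-helical fraction of a conformation
#'
#' Fraction of non-terminal residues whose phi angle lies strictly between
#' -120 and -30 degrees and whose psi angle lies strictly between -60 and
#' 30 degrees (boundary values count as non-helical).
#'
#' @param protein a \code{cg_protein} with at least 3 residues.
#' @return fraction in [0, 1].
#' @export
helix_fraction <- function(protein) {
  r <- n_residues(protein)
  if (r < 3L) stop("at least 3 residues required")
  dih <- peptide_dihedrals(protein)
  i <- 2:(r - 1L)
  mean(dih$phi[i] > -120 & dih$phi[i] < -30 &
         dih$psi[i] > -60 & dih$psi[i] < 30)
}

#' Helix-fraction trace over a trajectory
#'
#' Per-snapshot helical fraction, optionally smoothed by averaging over a
#' window of \code{window} snapshots either side.
#'
#' @param trajectory a \code{cg_trajectory}.
#' @param window half-width of the smoothing window in snapshots (0 for
#'   the raw trace; the reference analysis uses 5).
#' @return numeric vector, one value per snapshot.
#' @export
helix_fraction_trace <- function(trajectory, window = 0L) {
  n <- dim(trajectory$coords)[1]
  raw <- vapply(seq_len(n), function(s)
    helix_fraction(trajectory_snapshot(trajectory, s)), numeric(1))
  if (window <= 0L) return(raw)
  vapply(seq_len(n), function(s) {
    lo <- max(1L, s - window)
    hi <- min(n, s + window)
    mean(raw[lo:hi])
  }, numeric(1))
}

# Distance of the energy minimum of the same-residue CA-SC table for an
# amino acid (bin-centre of the lowest stored value; exact ties resolve to
# the higher bin).
ca_sc_min_distance <- function(potential, aa) {
  row <- same_pair_row(aa, 2L, 4L)
  v <- potential$tables$same[row, ]
  centres <- bin_centres(potential$specs$same)
  centres[max(which(v == min(v)))]
}

#' Deterministic steepest-descent energy minimisation
#'
#' Moves beads along the force direction with a fixed step scale, capping
#' the per-bead displacement per step; velocity-free and deterministic.
#'
#' @param protein a \code{cg_protein}.
#' @param potential a \code{potential_set}.
#' @param steps number of descent steps.
#' @param step_scale displacement per unit force (Angstrom).
#' @param max_disp per-bead displacement cap per step (Angstrom).
#' @param freeze_backbone keep N, CA and C beads fixed.
#' @return list with the minimised \code{protein} and final \code{energy}.
#' @export
minimise_energy <- function(protein, potential, steps = 100L,
                            step_scale = 0.01, max_disp = 0.1,
                            freeze_backbone = FALSE) {
  sys <- cg_system(protein, potential)
  x <- protein$coords
  backbone <- rep(c(TRUE, TRUE, TRUE, FALSE), n_residues(protein))
  for (s in seq_len(steps)) {
    f <- force_apply(x, sys, force_state(x, sys, potential$tables))$force
    disp <- step_scale * f
    nrm <- sqrt(rowSums(disp^2))
    over <- nrm > max_disp
    if (any(over)) disp[over, ] <- disp[over, ] * (max_disp / nrm[over])
    if (freeze_backbone) disp[backbone, ] <- 0
    x <- x + disp
  }
  out <- cg_protein(protein$sequence, protein$ss, x)
  list(protein = out, energy = system_energy(x, sys, potential$tables))
}

#' Thread a sequence onto a native backbone and score it
#'
#' Backbone beads are copied from the native structure. Each sidechain
#' centroid is placed along the native CA-to-SC direction at the distance
#' of the minimum of the learned same-residue CA-SC potential for the new
#' amino acid. A brief deterministic energy minimisation is then run and
#' the final energy returned as the sequence's energy.
#'
#' @param native a \code{cg_protein} (supplies backbone, SC directions and
#'   secondary structure).
#' @param sequence candidate sequence, same length as the native.
#' @param potential a \code{potential_set}.
#' @param minimise_steps minimisation steps (default 100).
#' @param step_scale,max_disp minimiser parameters, see
#'   \code{\link{minimise_energy}}.
#' @param freeze_backbone restrict the minimisation to SC beads.
#' @return list with \code{energy} and the minimised threaded
#'   \code{protein}.
#' @export
thread_sequence <- function(native, sequence, potential,
                            minimise_steps = 100L, step_scale = 0.01,
                            max_disp = 0.1, freeze_backbone = FALSE) {
  r <- n_residues(native)
  if (nchar(sequence) != r) stop("sequence length does not match native")
  seq_v <- strsplit(sequence, "")[[1]]
  x <- native$coords
  for (i in seq_len(r)) {
    ca <- x[bead_index(i, 2L), ]
    sc <- x[bead_index(i, 4L), ]
    u <- sc - ca
    nu <- sqrt(sum(u^2))
    u <- if (nu > 1e-9) u / nu else
      pseudo_cbeta_dir(x[bead_index(i, 1L), ], ca, x[bead_index(i, 3L), ])
    x[bead_index(i, 4L), ] <- ca + ca_sc_min_distance(potential, seq_v[i]) * u
  }
  threaded <- cg_protein(sequence, native$ss, x)
  minimise_energy(threaded, potential, steps = minimise_steps,
                  step_scale = step_scale, max_disp = max_disp,
                  freeze_backbone = freeze_backbone)
}

# ---- fixed-backbone design ----------------------------------------------

#' Fixed-backbone design configuration
#'
#' @param n_trials total trial mutations (default 2,000).
#' @param accept_ceiling energy increase at or above which a mutation is
#'   always rejected (default 10).
#' @param p0 initial acceptance probability for uphill mutations (default
#'   0.25).
#' @param anneal_trials trials over which the uphill acceptance
#'   probability decays linearly from \code{p0} to 0 (default 1,000).
#' @param background named 20-vector of amino-acid frequencies
#'   (normalised; defaults to the PDB background composition).
#' @param minimise_steps threading minimisation steps per trial.
#' @param rng_seed integer seed.
#' @return a \code{design_config} list.
#' @export
design_config <- function(n_trials = 2000L, accept_ceiling = 10,
                          p0 = 0.25, anneal_trials = 1000L,
                          background = AA_BACKGROUND,
                          minimise_steps = 100L, rng_seed = 1L) {
  stopifnot(p0 >= 0, p0 <= 1, n_trials >= 1, anneal_trials >= 1)
  background <- background[AA1]
  if (any(is.na(background))) stop("background must cover all 20 amino acids")
  background <- background / sum(background)
  structure(list(n_trials = as.integer(n_trials),
                 accept_ceiling = accept_ceiling, p0 = p0,
                 anneal_trials = as.integer(anneal_trials),
                 background = background,
                 minimise_steps = as.integer(minimise_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "design_config")
}

#' Acceptance probability of the design Monte-Carlo rule
#'
#' Mutations lowering the energy are always accepted; increases of
#' \code{accept_ceiling} or more are always rejected; increases in
#' between are accepted with probability p0 * max(0, 1 - t / anneal),
#' which falls linearly from p0 at the first trial to 0 after
#' \code{anneal_trials} trials.
#'
#' @param dE energy change of the trial mutation.
#' @param trial 0-based trial index.
#' @param cfg a \code{design_config}.
#' @return acceptance probability in [0, 1] (vectorised).
#' @export
design_acceptance_prob <- function(dE, trial, cfg = design_config()) {
  p_lin <- cfg$p0 * pmax(0, 1 - trial / cfg$anneal_trials)
  ifelse(dE < 0, 1, ifelse(dE >= cfg$accept_ceiling, 0, p_lin))
}

#' Fixed-backbone sequence design
#'
#' Starts from a random sequence drawn from the background composition
#' and performs \code{n_trials} trial mutations: one uniformly chosen
#' position is mutated to an amino acid drawn from the background, the
#' new sequence is threaded onto the native backbone and scored, and the
#' mutation is accepted or rejected by
#' \code{\link{design_acceptance_prob}}.
#'
#' @param native a \code{cg_protein}.
#' @param potential a \code{potential_set}.
#' @param cfg a \code{design_config}.
#' @return list with the final \code{sequence}, \code{native_fraction}
#'   (positions matching the native sequence), final \code{energy} and a
#'   per-trial \code{trace} data frame.
#' @export
design_fixed_backbone <- function(native, potential, cfg = design_config()) {
  r <- n_residues(native)
  native_seq <- strsplit(native$sequence, "")[[1]]
  with_seed(cfg$rng_seed, {
    seq_v <- sample(AA1, r, replace = TRUE, prob = cfg$background)
    e_cur <- thread_sequence(native, paste(seq_v, collapse = ""), potential,
                             minimise_steps = cfg$minimise_steps)$energy
    accepted <- logical(cfg$n_trials)
    energies <- numeric(cfg$n_trials)
    for (t in seq_len(cfg$n_trials)) {
      pos <- sample.int(r, 1L)
      cand <- seq_v
      cand[pos] <- sample(AA1, 1L, prob = cfg$background)
      e_new <- thread_sequence(native, paste(cand, collapse = ""), potential,
                               minimise_steps = cfg$minimise_steps)$energy
      p <- design_acceptance_prob(e_new - e_cur, t - 1L, cfg)
      if (stats::runif(1L) < p) {
        seq_v <- cand
        e_cur <- e_new
        accepted[t] <- TRUE
      }
      energies[t] <- e_cur
    }
    list(sequence = paste(seq_v, collapse = ""),
         native_fraction = mean(seq_v == native_seq),
         energy = e_cur,
         trace = data.frame(trial = seq_len(cfg$n_trials),
                            accepted = accepted, energy = energies))
  })
}

#' Score decoy structures against a native
#'
#' Total energy of each structure under the potential; all structures must
#' share one sequence. Reports the native structure's rank (1 = lowest
#' energy, ties share the best rank) and its energy gap to the best
#' non-native decoy. With a flat potential all energies coincide and the
#' ranking is flagged as degenerate.
#'
#' @param structures list of \code{cg_protein} sharing a sequence.
#' @param potential a \code{potential_set}.
#' @param native_index which list element is the native structure.
#' @return list with \code{energies}, \code{native_rank},
#'   \code{energy_gap} (native minus best decoy; negative favours the
#'   native) and logical \code{degenerate}.
#' @export
score_decoys <- function(structures, potential, native_index = 1L) {
  seqs <- vapply(structures, function(p) p$sequence, character(1))
  if (length(unique(seqs)) != 1L) stop("structures differ in sequence")
  energies <- vapply(structures, total_energy, numeric(1),
                     potential = potential)
  degenerate <- max(energies) - min(energies) < 1e-12
  native_rank <- if (degenerate) NA_integer_ else
    as.integer(rank(energies, ties.method = "min")[native_index])
  gap <- if (degenerate) NA_real_ else
    energies[native_index] - min(energies[-native_index])
  list(energies = energies, native_rank = native_rank, energy_gap = gap,
       degenerate = degenerate)
}

#' Folding run from a secondary-structure start
#'
#' Builds the extended/helical starting conformation implied by the
#' secondary-structure string, runs a thermostatted simulation and
#' reports the per-snapshot C-alpha RMSD to a reference structure.
#'
#' @param sequence amino-acid sequence.
#' @param ss secondary-structure string (H residues start at
#'   phi = -60, psi = -60; E/C at phi = -120, psi = 140).
#' @param potential a \code{potential_set}.
#' @param config a \code{sim_config} (production defaults: Andersen
#'   thermostat, dt 0.004, temperature 0.015, coupling 25).
#' @param reference optional \code{cg_protein} for the RMSD trace;
#'   defaults to the starting conformation.
#' @param burn_in_snapshots snapshots discarded before taking the minimum
#'   RMSD.
#' @return list with the \code{trajectory}, \code{rmsd_trace} (C-alpha,
#'   one value per snapshot), \code{min_rmsd} over the post-burn-in
#'   window and the \code{start} conformation.
#' @export
fold <- function(sequence, ss, potential, config = sim_config(),
                 reference = NULL, burn_in_snapshots = 0L) {
  start <- build_start_conformation(sequence, ss, "predicted_ss")
  traj <- simulate(start, potential, config)
  ref <- if (is.null(reference)) start else reference
  r <- nchar(sequence)
  ca <- bead_index(seq_len(r), 2L)
  ref_ca <- ref$coords[ca, , drop = FALSE]
  n <- dim(traj$coords)[1]
  trace <- vapply(seq_len(n), function(s)
    kabsch_rmsd(traj$coords[s, ca, , drop = TRUE], ref_ca), numeric(1))
  post <- trace[seq_len(n) > burn_in_snapshots]
  if (!length(post)) stop("burn-in discards every snapshot")
  list(trajectory = traj, rmsd_trace = trace, min_rmsd = min(post),
       start = start)
}
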