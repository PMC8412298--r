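make_static_trajectory <- function(prot, n_snap) {
  coords <- array(NA_real_, c(n_snap, nrow(prot$coords), 3L))
  for (s in seq_len(n_snap)) coords[s, , ] <- prot$coords
  structure(list(coords = coords, sequence = prot$sequence, ss = prot$ss,
                 snapshot_interval = 1L, n_steps = n_snap - 1L, dt = 0.004),
            class = "cg_trajectory")
}

test_that("RMSF is zero for a static trajectory and errors on full burn-in", {
  prot <- make_mini_protein(6L, "H", 3L)
  traj <- make_static_trajectory(prot, 10L)
  expect_equal(rmsf(traj), rep(0, 6))
  expect_error(rmsf(traj, burn_in_snapshots = 9L), "fewer than 2")
})

test_that("RMSF of one oscillating residue matches the closed form", {
  prot <- make_mini_protein(10L, "HHHHEEEECC", 5L)
  traj <- make_static_trajectory(prot, 40L)
  delta <- 0.2
  ca5 <- bead_index(5L, "CA")
  for (s in seq_len(40L)) {
    traj$coords[s, ca5, 1] <- traj$coords[s, ca5, 1] +
      delta * (-1)^s
  }
  r <- rmsf(traj)
  # displacement sequence +/-delta has RMS exactly delta; the rigid
  # superposition of the 39 static beads absorbs almost none of it
  expect_equal(r[5], delta, tolerance = 0.05)
  expect_true(all(r[-5] < 0.05 * delta))
  # burn-in is honoured: discarding half the snapshots changes nothing here
  expect_equal(rmsf(traj, 10L)[5], delta, tolerance = 0.05)
})

test_that("helix fraction applies the open phi/psi box on non-terminal residues", {
  r <- 6L
  helical <- build_peptide(strrep("A", r),
                           peptide_geometry(rep(-60, r), rep(-45, r), 180))
  expect_equal(helix_fraction(helical), 1.0)
  boundary <- build_peptide(strrep("A", r),
                            peptide_geometry(rep(-120, r), rep(140, r), 180))
  expect_equal(helix_fraction(boundary), 0.0)
  # the box is open: just outside either boundary counts as non-helical,
  # just inside counts as helical
  outside <- build_peptide(strrep("A", r),
                           peptide_geometry(rep(-120.001, r), rep(0, r),
                                            180))
  expect_equal(helix_fraction(outside), 0.0)
  inside <- build_peptide(strrep("A", r),
                          peptide_geometry(rep(-119.999, r), rep(0, r),
                                           180))
  expect_equal(helix_fraction(inside), 1.0)
  # 5 residues, only residue 3 helical: 1 of 3 non-terminal residues
  phi <- c(-120, -120, -60, -120, -120)
  psi <- c(140, 140, -45, 140, 140)
  one <- build_peptide("AAAAA", peptide_geometry(phi, psi, 180))
  expect_equal(helix_fraction(one), 1 / 3)
  # rigid-body invariance
  th <- 0.9
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- cg_protein(one$sequence, one$ss,
                      sweep(one$coords %*% R, 2, c(-4, 2, 9), "+"))
  expect_equal(helix_fraction(moved), helix_fraction(one))
  two <- cg_protein("AA", "CC", matrix(rnorm(24), 8, 3))
  expect_error(helix_fraction(two), "at least 3")
})

test_that("threading the native sequence under a flat potential scores zero", {
  native <- make_mini_protein(3L, "HEC", 7L)
  pot <- init_potential_set()
  th <- thread_sequence(native, native$sequence, pot)
  expect_equal(th$energy, 0)
  # backbone untouched by SC placement (before and after a null minimisation)
  bb <- as.vector(t(sapply(1:3, function(i) bead_index(i, 1:3))))
  expect_equal(th$protein$coords[bb, ], native$coords[bb, ])
  th2 <- thread_sequence(native, native$sequence, pot)
  expect_identical(th$energy, th2$energy)
  expect_error(thread_sequence(native, "AA", pot), "length")
})

test_that("planted native wells make the native sequence optimal", {
  native <- make_mini_protein(3L, "CCC", 11L)
  seq_v <- strsplit(native$sequence, "")[[1]]
  stopifnot(!anyDuplicated(seq_v))
  sc_of <- function(i) native$coords[bead_index(i, "SC"), ]
  ca_of <- function(i) native$coords[bead_index(i, "CA"), ]
  # pin SC placement for the native amino acids at their native CA-SC
  # distances, and reward the native SC-SC type pairs at their native
  # separations with wells of depth 5
  entries <- lapply(1:3, function(i)
    toy_entry("same", same_pair_row(seq_v[i], "CA", "SC"), "harmonic",
              x0 = cg_distance(ca_of(i), sc_of(i)), k = 2))
  for (pair in list(c(1, 2), c(2, 3), c(1, 3))) {
    i <- pair[1]; j <- pair[2]
    cm <- paste0("close", j - i)
    entries <- c(entries, list(
      toy_entry(cm, close_pair_row(atom_type_index(seq_v[i], "SC"),
                                   atom_type_index(seq_v[j], "SC")),
                "harmonic", x0 = cg_distance(sc_of(i), sc_of(j)),
                k = 0.5, offset = -5)))
  }
  pot <- make_toy_potential(entries)
  e_native <- thread_sequence(native, native$sequence, pot,
                              minimise_steps = 10L)$energy
  worse <- 0L
  for (i in 1:3) {
    for (aa in setdiff(cglearn:::AA1, seq_v[i])) {
      mut <- seq_v
      mut[i] <- aa
      e_mut <- thread_sequence(native, paste(mut, collapse = ""), pot,
                               minimise_steps = 10L)$energy
      expect_gt(e_mut, e_native)
      worse <- worse + 1L
    }
  }
  expect_equal(worse, 57L)
})

test_that("the design acceptance rule reproduces its printed anchor points", {
  cfg <- design_config()
  expect_equal(design_acceptance_prob(5, 0L, cfg), 0.25)
  expect_equal(design_acceptance_prob(5, 500L, cfg), 0.125)
  expect_equal(design_acceptance_prob(5, 1500L, cfg), 0)
  expect_equal(design_acceptance_prob(-2, 1500L, cfg), 1)
  expect_equal(design_acceptance_prob(10, 0L, cfg), 0)
  expect_equal(design_acceptance_prob(12, 0L, cfg), 0)
})

test_that("Monte-Carlo acceptance frequencies match the piecewise rule", {
  cfg <- design_config(rng_seed = 5L)
  set.seed(123)
  n <- 20000L
  dE <- runif(n, -5, 15)
  trial <- sample(0:1999, n, replace = TRUE)
  p <- design_acceptance_prob(dE, trial, cfg)
  acc <- runif(n) < p
  for (band in list(c(0, 0.01), c(0.05, 0.15), c(0.15, 0.26), c(0.99, 1))) {
    sel <- p >= band[1] & p <= band[2]
    if (sum(sel) < 50) next
    exp_p <- mean(p[sel])
    se <- sqrt(exp_p * (1 - exp_p) / sum(sel))
    expect_lt(abs(mean(acc[sel]) - exp_p), max(4 * se, 1e-3))
  }
})

test_that("fixed-backbone design runs deterministically end to end", {
  native <- make_mini_protein(3L, "CCC", 11L)
  seq_v <- strsplit(native$sequence, "")[[1]]
  entries <- lapply(1:3, function(i) {
    d <- cg_distance(native$coords[bead_index(i, "CA"), ],
                     native$coords[bead_index(i, "SC"), ])
    toy_entry("same", same_pair_row(seq_v[i], "CA", "SC"), "harmonic",
              x0 = d, k = 0.5, offset = -5)
  })
  pot <- make_toy_potential(entries)
  cfg <- design_config(n_trials = 60L, anneal_trials = 30L,
                       minimise_steps = 5L, rng_seed = 2L)
  out1 <- design_fixed_backbone(native, pot, cfg)
  out2 <- design_fixed_backbone(native, pot, cfg)
  expect_identical(out1$sequence, out2$sequence)
  expect_gte(out1$native_fraction, 0)
  expect_lte(out1$native_fraction, 1)
  expect_equal(nrow(out1$trace), 60L)
  # energies never increase by accept_ceiling or more in one accepted step
  dE <- diff(out1$trace$energy)
  expect_true(all(dE < cfg$accept_ceiling))
})

test_that("decoy scoring ranks a planted native minimum first", {
  native <- make_mini_protein(4L, "CCCC", 13L)
  seq_v <- strsplit(native$sequence, "")[[1]]
  entries <- lapply(1:4, function(i) {
    d <- cg_distance(native$coords[bead_index(i, "CA"), ],
                     native$coords[bead_index(i, "SC"), ])
    toy_entry("same", same_pair_row(seq_v[i], "CA", "SC"), "harmonic",
              x0 = d, k = 5)
  })
  pot <- make_toy_potential(entries)
  set.seed(31)
  decoys <- lapply(1:20, function(k) {
    x <- native$coords
    for (i in 1:4) {
      b <- bead_index(i, "SC")
      x[b, ] <- x[b, ] + rnorm(3, 0, 0.3)
    }
    cg_protein(native$sequence, native$ss, x)
  })
  sc <- score_decoys(c(list(native), decoys), pot, native_index = 1L)
  expect_false(sc$degenerate)
  expect_equal(sc$native_rank, 1L)
  expect_lt(sc$energy_gap, 0)
  # identical decoy scores identically; flat potential flags degeneracy
  sc2 <- score_decoys(list(native, native), pot)
  expect_equal(sc2$energies[1], sc2$energies[2])
  scf <- score_decoys(c(list(native), decoys), init_potential_set())
  expect_true(scf$degenerate)
  expect_true(is.na(scf$native_rank))
  other <- make_mini_protein(4L, "HHHH", 1L)
  expect_error(score_decoys(list(native, other), pot), "sequence")
})

test_that("folding runs report an RMSD trace anchored at the start", {
  pot <- smooth_random_potential(0.02)
  cfg <- sim_config(dt = 0.004, n_steps = 200L, thermostat = "andersen",
                    temperature = 0.015, coupling = 25, rng_seed = 9L,
                    snapshot_interval = 50L)
  out <- fold("AELKA", "HHHHH", pot, cfg)
  expect_equal(out$rmsd_trace[1], 0)
  expect_length(out$rmsd_trace, 5L)
  out2 <- fold("AELKA", "HHHHH", pot, cfg)
  expect_identical(out$rmsd_trace, out2$rmsd_trace)
  expect_equal(out$min_rmsd, min(out$rmsd_trace))
})

test_that("helical torsion wells drive a coil toward helix", {
  # toy potential: wells at helical phi/psi in the H-state torsion tables
  # for every amino acid, acting on phi (id 1) and psi (id 2)
  entries <- list()
  for (aa in cglearn:::AA1) {
    entries <- c(entries, list(
      toy_entry("torsion", torsion_row_index(aa, 1L, "H"), "harmonic",
                x0 = -57, k = 4e-4),
      toy_entry("torsion", torsion_row_index(aa, 2L, "H"), "harmonic",
                x0 = -47, k = 4e-4)))
  }
  pot <- make_toy_potential(entries)
  start <- build_start_conformation("AELKAELK", strrep("H", 8),
                                    "random_coil", rng_seed = 21L)
  h0 <- helix_fraction(start)
  traj <- simulate(start, pot,
                   sim_config(dt = 0.02, n_steps = 4000L,
                              thermostat = "andersen", temperature = 0.002,
                              coupling = 25, rng_seed = 3L,
                              snapshot_interval = 1000L))
  h1 <- helix_fraction(trajectory_snapshot(traj, 5L))
  expect_gt(h1, h0)
})
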