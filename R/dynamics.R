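# Force computation from the binned tables, velocity Verlet integration,
# the Andersen thermostat and the production simulation driver.
#
# Forces follow the finite-difference rule F = (E(b-1) - E(b+1)) / 2 on the
# occupied bin of each term, applied as F times the analytic gradient of the
# term's geometric property (distance, bond angle or dihedral). Because each
# property is invariant under rigid-body motion, every term contributes zero
# net force and zero net torque identically.

#' Compile a protein + potential into a simulation system
#'
#' Precomputes the resolved interaction list, per-component term indices
#' and the scatter index used to accumulate per-term forces onto beads.
#' The result depends only on sequence/ss and the bin specifications, so it
#' can be reused as table values change during training.
#'
#' @param protein a \code{cg_protein}.
#' @param potential a \code{potential_set} (bin specifications are taken
#'   from it).
#' @return a \code{cg_system} list.
#' @export
cg_system <- function(protein, potential) {
  ints <- resolve_interactions(protein)
  pair_comp_idx <- lapply(PAIR_COMPONENTS,
                          function(cm) which(ints$pairs$comp == cm))
  names(pair_comp_idx) <- PAIR_COMPONENTS
  scatter_idx <- c(ints$pairs$i, ints$pairs$j,
                   ints$angles$i, ints$angles$j, ints$angles$k,
                   ints$torsions$i, ints$torsions$j,
                   ints$torsions$k, ints$torsions$l)
  structure(list(pairs = ints$pairs, angles = ints$angles,
                 torsions = ints$torsions,
                 pair_comp_idx = pair_comp_idx,
                 scatter_idx = scatter_idx,
                 n_beads = nrow(protein$coords),
                 masses = protein$masses,
                 specs = potential$specs),
            class = "cg_system")
}

# Occupied bins and finite-difference force magnitudes for every term
# (real coordinates only).
force_state <- function(X, sys, tables) {
  ob <- occupied_bins(X, sys, sys$specs)
  p <- sys$pairs
  F_pair <- numeric(length(p$row))
  for (cm in PAIR_COMPONENTS) {
    sel <- sys$pair_comp_idx[[cm]]
    if (length(sel)) {
      m <- tables[[cm]]
      nr <- nrow(m)
      r <- p$row[sel]; b <- ob$pair_bin[sel]
      F_pair[sel] <- 0.5 * (m[r + (b - 2L) * nr] - m[r + b * nr])
    }
  }
  m <- tables$angle; nr <- nrow(m)
  rb <- sys$angles$row; bb <- ob$angle_bin
  F_angle <- if (length(rb)) 0.5 * (m[rb + (bb - 2L) * nr] -
                                      m[rb + bb * nr]) else numeric(0)
  m <- tables$torsion; nr <- nrow(m)
  rt <- sys$torsions$row; bt <- ob$torsion_bin + 1L  # column in 142 layout
  F_tor <- if (length(rt)) 0.5 * (m[rt + (bt - 2L) * nr] -
                                    m[rt + bt * nr]) else numeric(0)
  bad <- c(which(!is.finite(F_pair)), which(!is.finite(F_angle)),
           which(!is.finite(F_tor)))
  if (length(bad)) {
    stop("non-finite force magnitude in term ", bad[1])
  }
  list(F_pair = F_pair, F_angle = F_angle, F_tor = F_tor,
       pair_bin = ob$pair_bin, angle_bin = ob$angle_bin,
       torsion_bin = ob$torsion_bin)
}

scatter_block <- function(contrib, idx, nb) {
  out <- matrix(0, nb, 3L)
  rs <- rowsum(contrib, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Apply frozen force magnitudes along property gradients at coordinates X
# (X may be complex; bins and magnitudes stay those of `state`).
force_apply <- function(X, sys, state, want_grads = FALSE) {
  gp <- grad_distances(X, sys$pairs$i, sys$pairs$j)
  ga <- grad_angles(X, sys$angles$i, sys$angles$j, sys$angles$k)
  gt <- grad_dihedrals(X, sys$torsions$i, sys$torsions$j,
                       sys$torsions$k, sys$torsions$l)
  contrib <- rbind(gp$gi * state$F_pair, gp$gj * state$F_pair,
                   ga$gi * state$F_angle, ga$gj * state$F_angle,
                   ga$gk * state$F_angle,
                   gt$gi * state$F_tor, gt$gj * state$F_tor,
                   gt$gk * state$F_tor, gt$gl * state$F_tor)
  force <- if (is.complex(contrib)) {
    scatter_block(Re(contrib), sys$scatter_idx, sys$n_beads) +
      1i * scatter_block(Im(contrib), sys$scatter_idx, sys$n_beads)
  } else {
    scatter_block(contrib, sys$scatter_idx, sys$n_beads)
  }
  out <- list(force = force, acc = force / sys$masses)
  if (want_grads) out$grads <- list(pair = gp, angle = ga, torsion = gt)
  out
}

system_forces <- function(X, sys, tables) {
  st <- force_state(X, sys, tables)
  fa <- force_apply(X, sys, st)
  list(force = fa$force, acc = fa$acc, state = st)
}

#' Forces and accelerations on every bead
#'
#' @param protein a \code{cg_protein}.
#' @param potential a \code{potential_set}.
#' @return list with \code{force} and \code{acc} (per-bead force divided by
#'   bead mass), each a (4R) x 3 matrix.
#' @export
compute_forces <- function(protein, potential) {
  sys <- cg_system(protein, potential)
  sf <- system_forces(protein$coords, sys, potential$tables)
  list(force = sf$force, acc = sf$acc)
}

#' Finite-difference force magnitude from a table
#'
#' F = (E(b-1) - E(b+1)) / 2 around the occupied bin; for torsion tables
#' the two pad values act as the out-of-range neighbours at the +/-180
#' degree seam.
#'
#' @param table_values numeric vector of stored energy values (length 140,
#'   or 142 for a padded torsion table).
#' @param bin_index occupied bin (1..140).
#' @param periodic_pad whether \code{table_values} carries pads.
#' @return force magnitude.
#' @export
force_magnitude <- function(table_values, bin_index, periodic_pad = FALSE) {
  k <- if (periodic_pad) bin_index + 1L else bin_index
  0.5 * (table_values[k - 1L] - table_values[k + 1L])
}

# ---- integration --------------------------------------------------------

#' Simulation configuration
#'
#' @param dt time step (unitless model time; 0.02 for training, 0.004 for
#'   production).
#' @param n_steps number of integration steps.
#' @param thermostat "none" (NVE) or "andersen" (NVT).
#' @param temperature Andersen redraw standard deviation (default 0.015).
#' @param coupling Andersen coupling constant (default 25); the per-bead
#'   collision probability per step is dt / coupling.
#' @param rng_seed integer seed controlling thermostat draws and optional
#'   starting velocities.
#' @param snapshot_interval record a snapshot every this many steps.
#' @param start_velocity_sd standard deviation of the Normal(0, sd)
#'   starting velocities (0 keeps the beads initially at rest).
#' @param divergence_bound coordinates beyond this magnitude (Angstrom)
#'   abort the run with an error.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(dt = 0.004, n_steps = 1000L,
                       thermostat = c("andersen", "none"),
                       temperature = 0.015, coupling = 25,
                       rng_seed = 1L, snapshot_interval = 100L,
                       start_velocity_sd = 0, divergence_bound = 1e4) {
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0, n_steps >= 1, snapshot_interval >= 1)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 thermostat = thermostat, temperature = temperature,
                 coupling = coupling, rng_seed = as.integer(rng_seed),
                 snapshot_interval = as.integer(snapshot_interval),
                 start_velocity_sd = start_velocity_sd,
                 divergence_bound = divergence_bound),
            class = "sim_config")
}

#' One velocity Verlet step
#'
#' x(t+dt) = x(t) + v(t) dt + a(t) dt^2 / 2, then new accelerations from
#' \code{accel_fn}, then v(t+dt) = v(t) + (a(t) + a(t+dt)) dt / 2.
#'
#' @param state list with matrices \code{x}, \code{v}, \code{a} and integer
#'   \code{step}; \code{a} must be consistent with \code{x}.
#' @param config a \code{sim_config} (only \code{dt} is used).
#' @param accel_fn function mapping coordinates to accelerations.
#' @return the advanced state.
#' @export
velocity_verlet_step <- function(state, config, accel_fn) {
  dt <- config$dt
  x1 <- state$x + state$v * dt + 0.5 * state$a * dt * dt
  a1 <- accel_fn(x1)
  v1 <- state$v + 0.5 * (state$a + a1) * dt
  list(x = x1, v = v1, a = a1, step = state$step + 1L)
}

#' One Andersen thermostat application
#'
#' Each bead independently suffers a collision with probability
#' dt / coupling; a colliding bead has all three velocity components
#' redrawn iid from Normal(0, temperature). Draws come from the current
#' RNG stream.
#'
#' @param state list with velocity matrix \code{v} (other entries pass
#'   through).
#' @param config a \code{sim_config} with thermostat parameters.
#' @return the state with updated velocities and an integer
#'   \code{n_collisions} field.
#' @export
andersen_step <- function(state, config) {
  nb <- nrow(state$v)
  hit <- stats::runif(nb) < config$dt / config$coupling
  n <- sum(hit)
  if (n > 0L) {
    state$v[hit, ] <- stats::rnorm(3L * n, 0, config$temperature)
  }
  state$n_collisions <- n
  state
}

#' Run a simulation
#'
#' Velocity Verlet integration of a coarse-grained protein under a
#' potential set, in the NVE ensemble (thermostat "none") or NVT with the
#' Andersen thermostat applied after each velocity update. Snapshots
#' (coordinates plus potential and kinetic energy) are recorded every
#' \code{snapshot_interval} steps, including the initial conformation.
#'
#' @param protein a \code{cg_protein} supplying the start coordinates.
#' @param potential a \code{potential_set}.
#' @param config a \code{sim_config}.
#' @return a \code{cg_trajectory}: snapshot coordinate array
#'   (snapshots x beads x 3), energies, and run metadata.
#' @export
simulate <- function(protein, potential, config) {
  sys <- cg_system(protein, potential)
  tables <- potential$tables
  nb <- sys$n_beads
  n_snap <- config$n_steps %/% config$snapshot_interval + 1L
  coords <- array(NA_real_, c(n_snap, nb, 3L))
  e_pot <- e_kin <- numeric(n_snap)
  collisions <- 0L
  with_seed(config$rng_seed, {
    x <- protein$coords
    v <- if (config$start_velocity_sd > 0) {
      matrix(stats::rnorm(3L * nb, 0, config$start_velocity_sd), nb, 3L)
    } else {
      matrix(0, nb, 3L)
    }
    a <- system_forces(x, sys, tables)$acc
    coords[1L, , ] <- x
    e_pot[1L] <- system_energy(x, sys, tables)
    e_kin[1L] <- 0.5 * sum(sys$masses * v * v)
    st <- list(x = x, v = v, a = a, step = 0L)
    accel_fn <- function(xx) system_forces(xx, sys, tables)$acc
    for (s in seq_len(config$n_steps)) {
      st <- velocity_verlet_step(st, config, accel_fn)
      if (config$thermostat == "andersen") {
        st <- andersen_step(st, config)
        collisions <- collisions + st$n_collisions
      }
      if (max(abs(st$x)) > config$divergence_bound) {
        stop("coordinates diverged beyond ", config$divergence_bound,
             " Angstrom at step ", s, "; try a smaller time step dt")
      }
      if (s %% config$snapshot_interval == 0L) {
        k <- s %/% config$snapshot_interval + 1L
        coords[k, , ] <- st$x
        e_pot[k] <- system_energy(st$x, sys, tables)
        e_kin[k] <- 0.5 * sum(sys$masses * st$v * st$v)
      }
    }
  })
  structure(list(coords = coords, e_pot = e_pot, e_kin = e_kin,
                 sequence = protein$sequence, ss = protein$ss,
                 masses = sys$masses,
                 snapshot_interval = config$snapshot_interval,
                 n_steps = config$n_steps, dt = config$dt,
                 n_collisions = collisions),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "cg_trajectory: %d snapshots of %d beads (%d steps, dt = %g)\n",
    dim(x$coords)[1], dim(x$coords)[2], x$n_steps, x$dt))
  invisible(x)
}

#' Extract one snapshot of a trajectory as a protein
#' @param trajectory a \code{cg_trajectory}.
#' @param snapshot snapshot index (1-based).
#' @return a \code{cg_protein}.
#' @export
trajectory_snapshot <- function(trajectory, snapshot) {
  cg_protein(trajectory$sequence, trajectory$ss,
             trajectory$coords[snapshot, , ])
}
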