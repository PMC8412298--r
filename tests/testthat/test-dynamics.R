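test_that("finite-difference force magnitudes follow the two-bin rule", {
  v <- rep(0, 140)
  v[49] <- 1.0; v[51] <- 0.5
  expect_equal(force_magnitude(v, 50L), 0.25)
  expect_true(all(vapply(2:139, function(b)
    force_magnitude(rep(3, 140), b), 1) == 0))
  # torsion seam: pads act as the outer neighbours
  tv <- rep(0, 142)
  tv[1] <- 0.8           # low pad
  tv[3] <- 0.2           # bin 2
  expect_equal(force_magnitude(tv, 1L, periodic_pad = TRUE),
               0.5 * (0.8 - 0.2))
  tv2 <- rep(0, 142)
  tv2[140] <- 0.6        # bin 139
  tv2[142] <- 0.1        # high pad
  expect_equal(force_magnitude(tv2, 140L, periodic_pad = TRUE),
               0.5 * (0.6 - 0.1))
})

test_that("a repulsive table (energy descending with distance) pushes beads apart", {
  # plant descending energy on the ALA CA-SC table and check the 1-D sign
  prot <- cg_protein("A", "C",
                     rbind(c(0, 0, 0), c(1.46, 0, 0), c(1.98, 1.43, 0),
                           c(1.46, -2.0, 0)))
  pot <- init_potential_set()
  centres <- bin_centres(pot$specs$same)
  pot$tables$same[same_pair_row("A", "CA", "SC"), ] <- -centres  # dE/dd < 0
  f <- compute_forces(prot, pot)$force
  ca <- prot$coords[2, ]; sc <- prot$coords[4, ]
  u <- (sc - ca) / cg_distance(sc, ca)
  expect_gt(sum(f[4, ] * u), 0)    # SC pushed away from CA
  expect_lt(sum(f[2, ] * u), 0)    # CA pushed away from SC
  # and an ascending table attracts
  pot$tables$same[same_pair_row("A", "CA", "SC"), ] <- centres
  f <- compute_forces(prot, pot)$force
  expect_lt(sum(f[4, ] * u), 0)
})

test_that("zero potential gives zero forces everywhere", {
  prot <- make_mini_protein(5L, "HHECC", 8L)
  f <- compute_forces(prot, init_potential_set())
  expect_true(all(f$force == 0))
  expect_true(all(f$acc == 0))
})

test_that("internal forces carry zero net force and torque", {
  pot <- smooth_random_potential()
  for (seed in 1:4) {
    prot <- make_mini_protein(4L + seed, "HCEH", seed)
    f <- compute_forces(prot, pot)$force
    expect_lt(max(abs(colSums(f))), 1e-9)
    tq <- colSums(cglearn:::cross3(prot$coords, f))
    expect_lt(max(abs(tq)), 1e-9)
  }
})

test_that("velocity Verlet is exact for ballistic and constant-force motion", {
  cfg <- sim_config(dt = 0.02, n_steps = 1L, thermostat = "none")
  x0 <- matrix(0, 2, 3)
  v0 <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3)
  st <- list(x = x0, v = v0, a = matrix(0, 2, 3), step = 0L)
  zero_acc <- function(x) matrix(0, 2, 3)
  for (s in 1:10) st <- velocity_verlet_step(st, cfg, zero_acc)
  expect_equal(st$x, x0 + v0 * 10 * 0.02)

  a0 <- matrix(c(0, 0.5, 0, 0, 0, -1), 2, 3)
  const_acc <- function(x) a0
  st <- list(x = x0, v = v0, a = const_acc(x0), step = 0L)
  n <- 200L
  for (s in seq_len(n)) st <- velocity_verlet_step(st, cfg, const_acc)
  t_tot <- n * 0.02
  expect_equal(st$x, x0 + v0 * t_tot + 0.5 * a0 * t_tot^2,
               tolerance = 1e-12)
  expect_equal(st$v, v0 + a0 * t_tot, tolerance = 1e-12)
})

test_that("NVE integration is time-reversible", {
  prot <- make_mini_protein(4L, "H", 2L)
  pot <- smooth_random_potential()
  sys <- cg_system(prot, pot)
  nb <- nrow(prot$coords)
  set.seed(9)
  v0 <- matrix(rnorm(3 * nb, 0, 0.05), nb, 3)
  xs <- cglearn:::simulate_nve_tape(sys, pot$tables, prot$coords, v0,
                                    200L, 0.01)
  # recover the final velocity by replaying the last step
  x_end <- xs[201, , ]
  accel <- function(x) cglearn:::system_forces(x, sys, pot$tables)$acc
  v <- v0
  a <- accel(prot$coords)
  x <- prot$coords
  for (s in 1:200) {
    x1 <- x + v * 0.01 + 0.5 * a * 1e-4
    a1 <- accel(x1)
    v <- v + 0.5 * (a + a1) * 0.01
    x <- x1; a <- a1
  }
  xs_back <- cglearn:::simulate_nve_tape(sys, pot$tables, x, -v, 200L, 0.01)
  expect_lt(max(abs(xs_back[201, , ] - prot$coords)), 1e-8)
})

test_that("NVE total energy is conserved on a harmonic toy bond", {
  # 1-residue system with one harmonic table; energy bookkeeping uses the
  # piecewise-linear potential implied by the per-bin forces
  prot <- cg_protein("A", "C",
                     rbind(c(0, 0, 0), c(1.46, 0, 0), c(1.98, 1.43, 0),
                           c(1.46, -2.3, 0)))
  pot <- make_toy_potential(list(
    toy_entry("same", same_pair_row("A", "CA", "SC"), "harmonic",
              x0 = 2.0, k = 2)))
  sys <- cg_system(prot, pot)
  # independent oracle: U(d) from cumulative integration of the bin forces
  spec <- pot$specs$same
  w <- spec$width
  tab <- pot$tables$same[same_pair_row("A", "CA", "SC"), ]
  Fb <- numeric(140)
  Fb[2:139] <- 0.5 * (tab[1:138] - tab[3:140])
  # U at the lower edge of each bin (bin b spans lo+(b-1)w .. lo+bw),
  # integrated from the per-bin constant forces, anchored at bin 2
  U_edges <- numeric(141)
  for (b in 2:139) U_edges[b + 1] <- U_edges[b] - Fb[b] * w
  U_of <- function(d) {
    b <- min(max(floor((d - spec$lo) / w) + 1, 2), 139)
    U_edges[b] - Fb[b] * (d - (spec$lo + (b - 1) * w))
  }
  masses <- prot$masses
  accel <- function(x) cglearn:::system_forces(x, sys, pot$tables)$acc
  dt <- 0.005
  x <- prot$coords
  v <- matrix(0, 4L, 3)
  a <- accel(x)
  etot <- numeric(0)
  for (s in 1:10000) {
    x1 <- x + v * dt + 0.5 * a * dt * dt
    a1 <- accel(x1)
    v <- v + 0.5 * (a + a1) * dt
    x <- x1; a <- a1
    if (s %% 100 == 0) {
      etot <- c(etot, 0.5 * sum(masses * v * v) +
                  U_of(cg_distance(x[2, ], x[4, ])))
    }
  }
  e_early <- mean(etot[1:10])
  e_late <- mean(etot[91:100])
  scale <- max(abs(e_early), max(etot) - min(etot), 0.01)
  expect_lt(abs(e_late - e_early) / scale, 0.01)
})

test_that("the Andersen thermostat redraws at the configured rate", {
  cfg <- sim_config(dt = 0.004, coupling = 25, temperature = 0.015)
  expect_equal(cfg$dt / cfg$coupling, 1.6e-4)
  # temperature 0: redrawn velocities are exactly zero
  cfg0 <- sim_config(dt = 1, coupling = 1, temperature = 0)
  st <- list(v = matrix(1, 50, 3))
  set.seed(1)
  st0 <- andersen_step(st, cfg0)
  expect_equal(st0$n_collisions, 50L)
  expect_true(all(st0$v == 0))
  # empirical collision rate over 1e6 bead-steps within 3 sigma
  nb <- 100L
  steps <- 10000L
  st <- list(v = matrix(0, nb, 3))
  hits <- 0L
  set.seed(77)
  for (s in seq_len(steps)) {
    st <- andersen_step(st, cfg)
    hits <- hits + st$n_collisions
  }
  p <- cfg$dt / cfg$coupling
  n_tot <- as.numeric(nb) * steps
  expect_lt(abs(hits - n_tot * p), 3 * sqrt(n_tot * p * (1 - p)))
})

test_that("simulations are deterministic, inert when unforced, and guarded", {
  prot <- make_mini_protein(4L, "C", 6L)
  pot <- init_potential_set()
  cfg <- sim_config(dt = 0.004, n_steps = 100L, thermostat = "none",
                    snapshot_interval = 20L)
  traj <- simulate(prot, pot, cfg)
  expect_equal(dim(traj$coords)[1], 6L)  # floor(100/20) + 1
  for (s in 1:6) expect_equal(traj$coords[s, , ], prot$coords)

  cfgA <- sim_config(dt = 0.004, n_steps = 200L, thermostat = "andersen",
                     temperature = 0.05, coupling = 1, rng_seed = 5L,
                     snapshot_interval = 50L)
  potR <- smooth_random_potential()
  t1 <- simulate(prot, potR, cfgA)
  t2 <- simulate(prot, potR, cfgA)
  expect_identical(t1$coords, t2$coords)
  expect_gt(t1$n_collisions, 0L)

  # a stiff table with a huge time step diverges with a clear error
  steep <- make_toy_potential(list(
    toy_entry("same", same_pair_row("A", "CA", "SC"), "harmonic",
              x0 = 2.0, k = 500)))
  p1 <- cg_protein("A", "C",
                   rbind(c(0, 0, 0), c(1.46, 0, 0), c(1.98, 1.43, 0),
                         c(1.46, -3.4, 0)))
  expect_error(
    simulate(p1, steep, sim_config(dt = 5, n_steps = 1000L,
                                   thermostat = "none",
                                   divergence_bound = 1e3)),
    "smaller time step")
})
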