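# Reverse-mode (adjoint) differentiation of the structural loss through
# the velocity Verlet integration, with respect to every table value that
# shaped a force during the run.
#
# The forward NVE pass stores the coordinate history. The backward pass
# carries adjoints of coordinates, velocities and accelerations through the
# reversed update equations. At each step it needs two vector products
# with the force field f(x) = sum_k F_k * grad g_k(x):
#   * with respect to table values: each term is linear in the two
#     neighbour entries E(b-1), E(b+1) with coefficients +1/2 and -1/2
#     times (cotangent . grad g_k);
#   * with respect to coordinates: since bin selection is frozen in the
#     backward pass, f is the gradient of a scalar and its Jacobian is
#     symmetric, so the needed transpose-Jacobian product equals the
#     directional derivative of f along the cotangent. That directional
#     derivative is evaluated exactly (to machine precision) by a
#     complex-step evaluation f(x + i h w), h = 1e-20, whose imaginary
#     part divided by h is the derivative; the gradient formulas contain
#     only arithmetic and square roots and so are complex-analytic.
# Bin selection and clamping are treated as constants of the backward pass;
# gradients flow only through the stored energy values entering F.

CSTEP_H <- 1e-20

# Forward NVE pass recording all coordinates. Returns the (n_steps+1) x
# beads x 3 coordinate array.
simulate_nve_tape <- function(sys, tables, x0, v0, n_steps, dt,
                              divergence_bound = 1e4) {
  nb <- sys$n_beads
  xs <- array(NA_real_, c(n_steps + 1L, nb, 3L))
  xs[1L, , ] <- x0
  x <- x0
  v <- v0
  a <- system_forces(x, sys, tables)$acc
  for (s in seq_len(n_steps)) {
    x1 <- x + v * dt + 0.5 * a * dt * dt
    a1 <- system_forces(x1, sys, tables)$acc
    v <- v + 0.5 * (a + a1) * dt
    x <- x1
    a <- a1
    if (max(abs(x)) > divergence_bound) {
      stop("coordinates diverged beyond ", divergence_bound,
           " Angstrom at step ", s, "; try a smaller time step dt")
    }
    xs[s + 1L, , ] <- x
  }
  xs
}

# Per-term dot products of a bead-space cotangent with the property
# gradients: returns one scalar per pair/angle/torsion term.
cotangent_dots <- function(w, sys, grads) {
  p <- sys$pairs; a <- sys$angles; t <- sys$torsions
  dp <- dot3(w[p$i, , drop = FALSE], Re(grads$pair$gi)) +
    dot3(w[p$j, , drop = FALSE], Re(grads$pair$gj))
  da <- if (length(a$i)) {
    dot3(w[a$i, , drop = FALSE], Re(grads$angle$gi)) +
      dot3(w[a$j, , drop = FALSE], Re(grads$angle$gj)) +
      dot3(w[a$k, , drop = FALSE], Re(grads$angle$gk))
  } else numeric(0)
  dt_ <- if (length(t$i)) {
    dot3(w[t$i, , drop = FALSE], Re(grads$torsion$gi)) +
      dot3(w[t$j, , drop = FALSE], Re(grads$torsion$gj)) +
      dot3(w[t$k, , drop = FALSE], Re(grads$torsion$gk)) +
      dot3(w[t$l, , drop = FALSE], Re(grads$torsion$gl))
  } else numeric(0)
  list(pair = dp, angle = da, torsion = dt_)
}

# Append the table-value gradient keys/values implied by one backward-step
# cotangent to the per-component accumulators (environment `acc` holding
# idx[[cm]] / val[[cm]] lists).
accumulate_table_grads <- function(acc, sys, st, dots, tables) {
  for (cm in PAIR_COMPONENTS) {
    sel <- sys$pair_comp_idx[[cm]]
    if (!length(sel)) next
    nr <- nrow(tables[[cm]])
    r <- sys$pairs$row[sel]
    b <- st$pair_bin[sel]
    d <- dots$pair[sel]
    acc$idx[[cm]][[length(acc$idx[[cm]]) + 1L]] <-
      c(r + (b - 2L) * nr, r + b * nr)
    acc$val[[cm]][[length(acc$val[[cm]]) + 1L]] <- c(0.5 * d, -0.5 * d)
  }
  if (length(sys$angles$row)) {
    nr <- nrow(tables$angle)
    r <- sys$angles$row
    b <- st$angle_bin
    d <- dots$angle
    acc$idx$angle[[length(acc$idx$angle) + 1L]] <-
      c(r + (b - 2L) * nr, r + b * nr)
    acc$val$angle[[length(acc$val$angle) + 1L]] <- c(0.5 * d, -0.5 * d)
  }
  if (length(sys$torsions$row)) {
    nr <- nrow(tables$torsion)
    r <- sys$torsions$row
    b <- st$torsion_bin + 1L
    d <- dots$torsion
    acc$idx$torsion[[length(acc$idx$torsion) + 1L]] <-
      c(r + (b - 2L) * nr, r + b * nr)
    acc$val$torsion[[length(acc$val$torsion) + 1L]] <- c(0.5 * d, -0.5 * d)
  }
  invisible(acc)
}

# VJP of the acceleration field at coordinates X against cotangent `abar`
# (adjoint of the accelerations). Returns the coordinate-space adjoint
# contribution and records table gradients.
acceleration_vjp <- function(X, abar, sys, tables, acc) {
  w <- abar / sys$masses
  st <- force_state(X, sys, tables)
  Z <- X + (0 + 1i) * CSTEP_H * w
  fa <- force_apply(Z, sys, st, want_grads = TRUE)
  dots <- cotangent_dots(w, sys, fa$grads)
  accumulate_table_grads(acc, sys, st, dots, tables)
  Im(fa$force) / CSTEP_H
}

#' Loss, RMSD and parameter gradients of a native-start NVE simulation
#'
#' Runs an NVE simulation from the protein's coordinates, computes the
#' final-frame all-bead Kabsch RMSD to those coordinates (R_f) and the
#' loss log(1 + R_f), and backpropagates the loss through the integrator
#' to obtain the gradient with respect to every potential table value.
#'
#' @param protein a \code{cg_protein} (native structure; simulation start).
#' @param potential a \code{potential_set}.
#' @param n_steps number of NVE steps.
#' @param dt time step (default 0.02, the training value).
#' @param v0 starting velocity matrix (beads x 3); zero if omitted.
#' @param sys optional precompiled \code{cg_system} for reuse.
#' @return list with \code{rf}, \code{loss}, \code{final_coords} and
#'   \code{grad}, a per-component list of sparse gradients
#'   (\code{idx} into the table matrix, \code{val}).
#' @export
rf_loss_grad <- function(protein, potential, n_steps, dt = 0.02,
                         v0 = NULL, sys = NULL) {
  if (is.null(sys)) sys <- cg_system(protein, potential)
  tables <- potential$tables
  nb <- sys$n_beads
  x0 <- protein$coords
  if (is.null(v0)) v0 <- matrix(0, nb, 3L)
  xs <- simulate_nve_tape(sys, tables, x0, v0, n_steps, dt)
  xn <- xs[n_steps + 1L, , ]
  rf <- kabsch_rmsd(xn, x0)
  loss <- log(1 + rf)

  acc <- new.env(parent = emptyenv())
  acc$idx <- acc$val <- stats::setNames(
    rep(list(list()), length(tables)), names(tables))

  xb <- kabsch_rmsd_grad(xn, x0) / (1 + rf)
  vb <- matrix(0, nb, 3L)
  ab <- matrix(0, nb, 3L)
  for (t in seq(n_steps - 1L, 0L)) {
    # v(t+1) = v(t) + (a(t) + a(t+1)) dt/2
    vb_t <- vb
    ab_t <- 0.5 * dt * vb
    ab <- ab + 0.5 * dt * vb
    # a(t+1) = A(x(t+1))
    xb <- xb + acceleration_vjp(xs[t + 2L, , ], ab, sys, tables, acc)
    # x(t+1) = x(t) + v(t) dt + a(t) dt^2/2
    vb <- vb_t + dt * xb
    ab <- ab_t + 0.5 * dt * dt * xb
  }
  # a(0) = A(x(0)): remaining adjoint of the initial accelerations
  w <- ab / sys$masses
  st0 <- force_state(x0, sys, tables)
  fa0 <- force_apply(x0, sys, st0, want_grads = TRUE)
  dots0 <- cotangent_dots(w, sys, fa0$grads)
  accumulate_table_grads(acc, sys, st0, dots0, tables)

  grad <- lapply(names(tables), function(cm) {
    if (!length(acc$idx[[cm]])) return(list(idx = integer(0),
                                            val = numeric(0)))
    keys <- unlist(acc$idx[[cm]], use.names = FALSE)
    vals <- unlist(acc$val[[cm]], use.names = FALSE)
    agg <- rowsum(vals, keys)
    list(idx = as.integer(rownames(agg)), val = as.numeric(agg))
  })
  names(grad) <- names(tables)
  list(rf = rf, loss = loss, final_coords = xn, grad = grad)
}
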