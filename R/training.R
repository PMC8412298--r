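# Kabsch superposition/RMSD, the structural loss, the Adam optimiser and
# the training loop (native-start NVE simulations, step-count curriculum,
# gradient accumulation).

#' Minimal RMSD after optimal rigid superposition (Kabsch)
#'
#' Least-squares RMSD over proper rotations and translations (reflections
#' excluded via the SVD determinant sign rule, which also handles
#' degenerate point sets).
#'
#' @param X,Y numeric N x 3 coordinate matrices (N >= 2).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(X, Y) {
  fit <- kabsch_fit(X, Y)
  sqrt(sum((fit$Xc %*% fit$R - fit$Yc)^2) / nrow(X))
}

kabsch_fit <- function(X, Y) {
  if (!all(dim(X) == dim(Y))) stop("coordinate sets differ in size")
  if (nrow(X) < 2L) stop("at least 2 points required")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(t(Xc) %*% Yc)
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(Xc = Xc, Yc = Yc, R = R)
}

# Gradient of kabsch_rmsd with respect to X. The optimal rotation and
# translation make the superposition residual stationary, so they may be
# held fixed when differentiating (envelope theorem).
kabsch_rmsd_grad <- function(X, Y) {
  fit <- kabsch_fit(X, Y)
  res <- fit$Xc %*% fit$R - fit$Yc
  rmsd <- sqrt(sum(res^2) / nrow(X))
  if (rmsd < 1e-12) return(matrix(0, nrow(X), 3L))
  (res %*% t(fit$R)) / (nrow(X) * rmsd)
}

#' Superpose coordinates onto a reference
#' @param X N x 3 coordinates to move.
#' @param onto N x 3 reference coordinates.
#' @return X rigidly transformed to minimise RMSD to \code{onto}.
#' @export
kabsch_superpose <- function(X, onto) {
  fit <- kabsch_fit(X, onto)
  sweep(fit$Xc %*% fit$R, 2, colMeans(onto), "+")
}

#' Structural training loss
#'
#' log(1 + R_f), where R_f is the all-bead Kabsch RMSD of the final
#' simulated conformation to the native structure.
#'
#' @param rf non-negative RMSD (Angstrom).
#' @return loss value.
#' @export
rf_loss <- function(rf) {
  if (any(rf < 0)) stop("R_f must be non-negative")
  log(1 + rf)
}

# ---- configuration ------------------------------------------------------

#' Training configuration
#'
#' Defaults reproduce the reference protocol: 45 epochs, gradients
#' accumulated over 100 proteins per update, Adam at learning rate 1e-4
#' reset to 5e-5 at epoch 38, simulations of 250 steps growing by 250
#' every 5 epochs to a cap of 2,000, starting velocities Normal(0, 0.1),
#' time step 0.02.
#'
#' @param epochs number of passes over the dataset.
#' @param accumulate proteins per optimiser update.
#' @param base_lr Adam learning rate.
#' @param reset_epoch epoch at whose start the optimiser state is
#'   discarded and the learning rate lowered (set above \code{epochs} to
#'   disable).
#' @param reset_lr learning rate after the reset.
#' @param steps_start,steps_increment,steps_every,steps_cap step-count
#'   curriculum: epoch e runs
#'   min(steps_start + steps_increment * floor((e-1)/steps_every),
#'   steps_cap) steps.
#' @param start_velocity_sd standard deviation of starting velocities.
#' @param dt integration time step.
#' @param rng_seed master seed; per-epoch and per-protein streams are
#'   derived from it.
#' @return a \code{training_config} list.
#' @export
training_config <- function(epochs = 45L, accumulate = 100L,
                            base_lr = 1e-4, reset_epoch = 38L,
                            reset_lr = 5e-5, steps_start = 250L,
                            steps_increment = 250L, steps_every = 5L,
                            steps_cap = 2000L, start_velocity_sd = 0.1,
                            dt = 0.02, rng_seed = 1L) {
  stopifnot(epochs >= 1, accumulate >= 1, base_lr > 0, reset_lr > 0,
            steps_start >= 1, steps_every >= 1, steps_cap >= steps_start,
            dt > 0)
  structure(list(epochs = as.integer(epochs),
                 accumulate = as.integer(accumulate),
                 base_lr = base_lr, reset_epoch = as.integer(reset_epoch),
                 reset_lr = reset_lr, steps_start = as.integer(steps_start),
                 steps_increment = as.integer(steps_increment),
                 steps_every = as.integer(steps_every),
                 steps_cap = as.integer(steps_cap),
                 start_velocity_sd = start_velocity_sd, dt = dt,
                 rng_seed = as.integer(rng_seed)),
            class = "training_config")
}

#' Simulation length for a training epoch
#' @param epoch epoch number (1-based).
#' @param config a \code{training_config}.
#' @return number of integration steps.
#' @export
steps_for_epoch <- function(epoch, config) {
  pmin(config$steps_start +
         config$steps_increment * ((epoch - 1L) %/% config$steps_every),
       config$steps_cap)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(tables, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(tables, function(m) array(0, dim(m))),
       v = lapply(tables, function(m) array(0, dim(m))),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_update <- function(tables, grads, state) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (cm in names(tables)) {
    g <- grads[[cm]]
    state$m[[cm]] <- state$beta1 * state$m[[cm]] + (1 - state$beta1) * g
    state$v[[cm]] <- state$beta2 * state$v[[cm]] + (1 - state$beta2) * g * g
    tables[[cm]] <- tables[[cm]] - state$lr *
      (state$m[[cm]] / bc1) / (sqrt(state$v[[cm]] / bc2) + state$eps)
  }
  list(tables = tables, state = state)
}

derive_seed <- function(master, epoch, item) {
  as.integer((as.numeric(master) + 100003 * epoch + 7919 * item) %%
               2147483647)
}

# ---- training loop ------------------------------------------------------

#' Learn potential parameters by differentiable simulation
#'
#' Each epoch simulates every protein (in a seeded random order) from its
#' native structure in the NVE ensemble with Normal(0, sd) starting
#' velocities, for the epoch's curriculum step count, and backpropagates
#' log(1 + R_f) through the integrator. Gradients are accumulated over
#' \code{accumulate} proteins (mean), then one Adam update is applied; a
#' partial batch at the end of an epoch is also applied. At
#' \code{reset_epoch} the optimiser state is re-created with the lower
#' learning rate. Simulations that diverge are skipped and logged.
#'
#' @param dataset list of \code{cg_protein} (native structures).
#' @param config a \code{training_config}.
#' @param validation optional list of \code{cg_protein} scored (no
#'   gradients) once per epoch.
#' @param potential optional warm-start \code{potential_set}; defaults to
#'   the zero-initialised set.
#' @param checkpoint_dir optional directory; when given, the potential is
#'   saved there after every epoch.
#' @param train_mask optional named list of 0/1 masks (same shapes as the
#'   tables); gradients are multiplied by the mask, freezing zero entries.
#' @param verbose print a line per epoch.
#' @return list with the trained \code{potential}, a per-epoch
#'   \code{log} data frame (epoch, steps, mean_train_rf, mean_val_rf,
#'   mean_loss, n_skipped) and the count of skipped simulations.
#' @export
train <- function(dataset, config, validation = NULL, potential = NULL,
                  checkpoint_dir = NULL, train_mask = NULL,
                  verbose = FALSE) {
  if (!length(dataset)) stop("empty dataset")
  if (is.null(potential)) potential <- init_potential_set()
  tables <- potential$tables
  systems <- lapply(dataset, cg_system, potential = potential)
  opt <- adam_init(tables, config$base_lr)
  zero_grads <- lapply(tables, function(m) array(0, dim(m)))
  log_rows <- vector("list", config$epochs)
  total_skipped <- 0L

  for (e in seq_len(config$epochs)) {
    if (e == config$reset_epoch) opt <- adam_init(tables, config$reset_lr)
    n_steps <- steps_for_epoch(e, config)
    order <- with_seed(derive_seed(config$rng_seed, e, 0L),
                       sample(length(dataset)))
    grads <- zero_grads
    n_acc <- 0L
    rfs <- losses <- numeric(0)
    skipped <- 0L
    flush <- function() {
      if (n_acc == 0L) return(invisible(NULL))
      g <- lapply(grads, function(m) m / n_acc)
      if (!is.null(train_mask)) {
        for (cm in names(g)) g[[cm]] <- g[[cm]] * train_mask[[cm]]
      }
      upd <- adam_update(tables, g, opt)
      tables <<- upd$tables
      opt <<- upd$state
      grads <<- zero_grads
      n_acc <<- 0L
    }
    for (idx in order) {
      prot <- dataset[[idx]]
      nb <- nrow(prot$coords)
      v0 <- with_seed(derive_seed(config$rng_seed, e, idx),
                      matrix(stats::rnorm(3L * nb, 0,
                                          config$start_velocity_sd),
                             nb, 3L))
      pot_now <- structure(list(tables = tables, specs = potential$specs,
                                version = potential$version),
                           class = "potential_set")
      res <- tryCatch(
        rf_loss_grad(prot, pot_now, n_steps, config$dt, v0,
                     sys = systems[[idx]]),
        error = function(err) err)
      if (inherits(res, "error")) {
        skipped <- skipped + 1L
        next
      }
      rfs <- c(rfs, res$rf)
      losses <- c(losses, res$loss)
      for (cm in names(grads)) {
        gi <- res$grad[[cm]]
        if (length(gi$idx)) {
          grads[[cm]][gi$idx] <- grads[[cm]][gi$idx] + gi$val
        }
      }
      n_acc <- n_acc + 1L
      if (n_acc == config$accumulate) flush()
    }
    flush()
    total_skipped <- total_skipped + skipped
    val_rf <- NA_real_
    if (!is.null(validation)) {
      pot_now <- structure(list(tables = tables, specs = potential$specs,
                                version = potential$version),
                           class = "potential_set")
      val_rf <- validate(validation, pot_now,
                         sim_steps = n_steps, dt = config$dt,
                         start_velocity_sd = config$start_velocity_sd,
                         rng_seed = config$rng_seed)
    }
    log_rows[[e]] <- data.frame(epoch = e, steps = n_steps,
                                mean_train_rf = mean(rfs),
                                mean_val_rf = val_rf,
                                mean_loss = mean(losses),
                                n_skipped = skipped)
    if (verbose) {
      message(sprintf("epoch %d: steps %d, mean train R_f %.3f", e,
                      n_steps, mean(rfs)))
    }
    if (!is.null(checkpoint_dir)) {
      pot_now <- structure(list(tables = tables, specs = potential$specs,
                                version = potential$version),
                           class = "potential_set")
      save_potential(pot_now,
                     file.path(checkpoint_dir,
                               sprintf("epoch_%03d.pot", e)))
    }
  }
  potential$tables <- tables
  list(potential = potential, log = do.call(rbind, log_rows),
       n_skipped = total_skipped)
}

#' Mean R_f of native-start simulations under a potential
#'
#' Same simulation protocol as training (NVE, seeded starting velocities)
#' but without gradients or parameter updates.
#'
#' @param dataset list of \code{cg_protein}.
#' @param potential a \code{potential_set}.
#' @param sim_steps steps per simulation.
#' @param dt time step.
#' @param start_velocity_sd starting velocity standard deviation.
#' @param rng_seed seed for the velocity draws.
#' @return mean all-bead R_f (Angstrom) over the dataset.
#' @export
validate <- function(dataset, potential, sim_steps, dt = 0.02,
                     start_velocity_sd = 0.1, rng_seed = 1L) {
  rfs <- vapply(seq_along(dataset), function(idx) {
    prot <- dataset[[idx]]
    sys <- cg_system(prot, potential)
    nb <- nrow(prot$coords)
    v0 <- if (start_velocity_sd > 0) {
      with_seed(derive_seed(rng_seed, 0L, idx),
                matrix(stats::rnorm(3L * nb, 0, start_velocity_sd), nb, 3L))
    } else {
      matrix(0, nb, 3L)
    }
    xs <- simulate_nve_tape(sys, potential$tables, prot$coords, v0,
                            sim_steps, dt)
    kabsch_rmsd(xs[sim_steps + 1L, , ], prot$coords)
  }, numeric(1))
  mean(rfs)
}
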