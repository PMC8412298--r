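# Shared fixtures and independent oracles used across the test files.

# Central finite-difference gradient of a scalar function of an N x 3
# coordinate matrix.
fd_coord_grad <- function(f, X, eps = 1e-6) {
  G <- X * 0
  for (i in seq_len(nrow(X))) {
    for (j in 1:3) {
      Xp <- X; Xm <- X
      Xp[i, j] <- Xp[i, j] + eps
      Xm[i, j] <- Xm[i, j] - eps
      G[i, j] <- (f(Xp) - f(Xm)) / (2 * eps)
    }
  }
  G
}

# Independent dihedral implementation: angle between the projections of the
# outer bonds onto the plane perpendicular to the central bond, signed by
# the triple product.
dihedral_projection_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  b2u <- b2 / sqrt(sum(b2^2))
  u <- -b1 + sum(b1 * b2u) * b2u   # component of p1->p2 reversed, in plane
  v <- b3 - sum(b3 * b2u) * b2u
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  tripl <- sum(cross_oracle(u, v) * b2u)
  if (tripl < 0) ang <- -ang
  ang
}

cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Brute-force minimal RMSD over proper rotations: quaternion-parameterised
# local minimisation from many random starts.
rmsd_quaternion_oracle <- function(X, Y, n_starts = 12L, seed = 99L) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) sqrt(sum((Xc %*% rot(q) - Yc)^2) / nrow(X))
  best <- Inf
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    q0 <- rnorm(4)
    o <- optim(q0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# All-atom style PDB ATOM line with the toy coordinates used by the
# structure-reading tests.
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM  ") {
  sprintf("%s%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          record, serial, name, resname, chain, resno, x, y, z)
}

# Small all-atom chain: ALA (CB at 1,1,1), VAL (three sidechain atoms) and
# GLY (backbone only).
toy_pdb_text <- function() {
  c(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.46, 0, 0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.0, 1.4, 0),
    pdb_atom_line(4, "O", "ALA", "A", 1, 2.0, 2.0, 1.0),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 1, 1, 1),
    pdb_atom_line(6, "N", "VAL", "A", 2, 3.3, 1.5, 0),
    pdb_atom_line(7, "CA", "VAL", "A", 2, 4.2, 2.6, 0.2),
    pdb_atom_line(8, "C", "VAL", "A", 2, 5.6, 2.1, 0.4),
    pdb_atom_line(9, "O", "VAL", "A", 2, 5.9, 0.9, 0.4),
    pdb_atom_line(10, "CB", "VAL", "A", 2, 4.1, 3.5, 1.4),
    pdb_atom_line(11, "CG1", "VAL", "A", 2, 5.0, 4.7, 1.3),
    pdb_atom_line(12, "CG2", "VAL", "A", 2, 4.3, 2.8, 2.75),
    pdb_atom_line(13, "N", "GLY", "A", 3, 6.4, 3.0, 0.6),
    pdb_atom_line(14, "CA", "GLY", "A", 3, 7.8, 2.7, 0.9),
    pdb_atom_line(15, "C", "GLY", "A", 3, 8.6, 3.9, 1.4),
    pdb_atom_line(16, "O", "GLY", "A", 3, 8.1, 5.0, 1.5),
    "END")
}

# Fill every table of a potential with small smooth deterministic values so
# simulations have non-trivial but stable forces.
smooth_random_potential <- function(scale = 0.05) {
  pot <- init_potential_set()
  for (cm in names(pot$tables)) {
    m <- pot$tables[[cm]]
    pot$tables[[cm]] <- matrix(
      scale * sin(outer(seq_len(nrow(m)) / 7, seq_len(ncol(m)) / 9, "+")),
      nrow(m), ncol(m))
  }
  pot
}

# Independent nearest-centre binning: search the 140 centres explicitly,
# resolve exact ties to the higher bin, clamp non-periodic results away
# from the outer bins.
oracle_bin <- function(value, lo, width, n_bins = 140L, periodic = FALSE) {
  centres <- lo + (seq_len(n_bins) - 0.5) * width
  if (periodic) {
    span <- n_bins * width
    d <- abs(value - centres) %% span
    d <- pmin(d, span - d)
  } else {
    d <- abs(value - centres)
  }
  k_set <- which(d == min(d))
  # an edge value belongs to the bin that starts there; across the
  # periodic seam that is bin 1
  k <- if (periodic && 1L %in% k_set && n_bins %in% k_set) 1L
       else max(k_set)
  if (!periodic) k <- min(max(k, 2L), n_bins - 1L)
  as.integer(k)
}
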