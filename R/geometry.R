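# Vector geometry on bead coordinates: distances, bond angles, dihedrals,
# their analytic gradients, and NeRF-style atom placement.
#
# Gradient helpers are written with arithmetic and sqrt only so they remain
# valid for complex inputs; the adjoint pass exploits this for exact
# directional derivatives via complex-step evaluation.

rad <- function(x) x * pi / 180
deg <- function(x) x * 180 / pi

#' Wrap angles in degrees to (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

dot3 <- function(a, b) {
  a[, 1] * b[, 1] + a[, 2] * b[, 2] + a[, 3] * b[, 3]
}

# sqrt that guards the real path against tiny negative round-off and exact
# zeros, while remaining analytic on the complex path.
safe_sqrt <- function(x) {
  if (is.complex(x)) return(sqrt(x))
  sqrt(pmax(x, 1e-24))
}

norm3 <- function(a) safe_sqrt(dot3(a, a))

#' Distance between two points
#' @param p1,p2 numeric length-3 vectors.
#' @return distance in the coordinate units (Angstrom).
#' @examples cg_distance(c(0, 0, 0), c(3, 4, 0))
#' @export
cg_distance <- function(p1, p2) sqrt(sum((p2 - p1)^2))

#' Bond angle at the central point
#'
#' Angle p1-p2-p3 in degrees, in [0, 180].
#' @param p1,p2,p3 numeric length-3 vectors; p2 is the vertex.
#' @return angle in degrees.
#' @examples cg_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
#' @export
cg_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cs <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  deg(acos(pmin(1, pmax(-1, cs))))
}

#' Dihedral angle over four points
#'
#' IUPAC sign convention, range (-180, 180]. Colinear (degenerate) input
#' yields 0 with attribute \code{degenerate = TRUE}.
#' @param p1,p2,p3,p4 numeric length-3 vectors.
#' @return dihedral angle in degrees.
#' @export
cg_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18) {
    return(structure(0, degenerate = TRUE))
  }
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  y <- sum(m1 * b2) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  ang <- deg(atan2(y, x))
  if (ang == -180) ang <- 180
  ang
}

# ---- vectorised values over index arrays --------------------------------

geom_distances <- function(X, i, j) {
  d <- X[j, , drop = FALSE] - X[i, , drop = FALSE]
  sqrt(dot3(d, d))
}

geom_angles <- function(X, i, j, k) {
  u <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  v <- X[k, , drop = FALSE] - X[j, , drop = FALSE]
  cs <- dot3(u, v) / (norm3(u) * norm3(v))
  deg(acos(pmin(1, pmax(-1, cs))))
}

geom_dihedrals <- function(X, i, j, k, l) {
  b1 <- X[j, , drop = FALSE] - X[i, , drop = FALSE]
  b2 <- X[k, , drop = FALSE] - X[j, , drop = FALSE]
  b3 <- X[l, , drop = FALSE] - X[k, , drop = FALSE]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  y <- dot3(cross3(n1, n2), b2) / norm3(b2)
  x <- dot3(n1, n2)
  ang <- deg(atan2(y, x))
  ang[ang == -180] <- 180
  ang
}

# ---- analytic gradients (per-atom, radians or Angstrom per Angstrom) ----
# Each returns a list of n x 3 matrices, one per involved atom, holding the
# gradient of the geometric property with respect to that atom's position.
# Distances in Angstrom per Angstrom, angles/dihedrals in radians per
# Angstrom; forces are F * gradient, which makes the net force and net
# torque of every term vanish identically.

grad_distances <- function(X, i, j) {
  d <- X[j, , drop = FALSE] - X[i, , drop = FALSE]
  r <- safe_sqrt(dot3(d, d))
  u <- d / r
  list(gi = -u, gj = u)
}

grad_angles <- function(X, i, j, k) {
  u <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  v <- X[k, , drop = FALSE] - X[j, , drop = FALSE]
  nu <- norm3(u); nv <- norm3(v)
  uh <- u / nu; vh <- v / nv
  cs <- dot3(uh, vh)
  sn <- safe_sqrt(1 - cs * cs)
  gi <- (uh * cs - vh) / (nu * sn)
  gk <- (vh * cs - uh) / (nv * sn)
  list(gi = gi, gj = -(gi + gk), gk = gk)
}

grad_dihedrals <- function(X, i, j, k, l) {
  b1 <- X[j, , drop = FALSE] - X[i, , drop = FALSE]
  b2 <- X[k, , drop = FALSE] - X[j, , drop = FALSE]
  b3 <- X[l, , drop = FALSE] - X[k, , drop = FALSE]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- norm3(b2)
  s1 <- dot3(n1, n1)
  s2 <- dot3(n2, n2)
  gi <- -n1 * (nb2 / s1)
  gl <- n2 * (nb2 / s2)
  p <- dot3(b1, b2) / (nb2 * nb2)
  q <- dot3(b3, b2) / (nb2 * nb2)
  gj <- -gi * (1 + p) + gl * q
  gk <- gi * p - gl * (1 + q)
  list(gi = gi, gj = gj, gk = gk, gl = gl)
}

# ---- NeRF atom placement ------------------------------------------------

#' Place an atom from internal coordinates
#'
#' Natural extension reference frame placement: given positions a, b, c,
#' returns d with bond length |cd| = bond, angle b-c-d = angle and dihedral
#' a-b-c-d = torsion.
#'
#' @param a,b,c numeric length-3 vectors of the three reference positions.
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees.
#' @param torsion dihedral in degrees.
#' @return numeric length-3 position.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- rad(angle)
  ta <- rad(torsion)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ta), bond * sin(th) * sin(ta))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Pseudo-C-beta direction from backbone bead positions: the tetrahedral
# direction from CA bisecting away from N and C, tilted out of the N-CA-C
# plane. Sign of the out-of-plane component selects the L-configuration.
pseudo_cbeta_dir <- function(n_pos, ca_pos, c_pos) {
  u1 <- n_pos - ca_pos
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c_pos - ca_pos
  u2 <- u2 / sqrt(sum(u2^2))
  bis <- u1 + u2
  bis <- bis / sqrt(sum(bis^2))
  perp <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  perp <- perp / sqrt(sum(perp^2))
  d <- -bis * sin(rad(IDEAL_GEOM$a_tetrahedral / 2)) -
    perp * cos(rad(IDEAL_GEOM$a_tetrahedral / 2))
  d / sqrt(sum(d^2))
}
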