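# Coarse-grained structure input/output: PDB reading into the 4-bead
# representation, PSIPRED ss2 parsing, the internal peptide builder, and
# the CG PDB dialect writer.

#' Construct a coarse-grained protein
#'
#' A residue is represented by four beads in fixed order N, CA, C, SC
#' (sidechain centroid). Coordinates are stored as a (4R) x 3 matrix with
#' row (r-1)*4 + b for bead b of residue r.
#'
#' @param sequence one-letter amino-acid string (standard 20 only).
#' @param ss per-residue secondary-structure string over H/E/C, same length
#'   as \code{sequence}.
#' @param coords numeric (4R) x 3 matrix of bead positions in Angstrom.
#' @param masses optional numeric vector of length 4R; computed from the
#'   sequence when omitted. Backbone beads have masses 15 (N), 13 (CA),
#'   28 (C); the SC mass is the summed heavy-atom mass of the sidechain
#'   (glycine: 10).
#' @return an object of class \code{cg_protein}.
#' @export
cg_protein <- function(sequence, ss, coords, masses = NULL) {
  seq_v <- strsplit(sequence, "")[[1]]
  ss_v <- strsplit(ss, "")[[1]]
  r <- length(seq_v)
  if (r == 0L) stop("empty sequence")
  if (length(ss_v) != r) stop("sequence and ss lengths differ")
  if (!all(seq_v %in% AA1)) {
    stop("non-standard residue(s): ",
         paste(unique(seq_v[!seq_v %in% AA1]), collapse = ", "))
  }
  if (!all(ss_v %in% SS_STATES)) stop("ss states must be H, E or C")
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3 || nrow(coords) != 4L * r) {
    stop("coords must be a numeric (4R) x 3 matrix")
  }
  ref_masses <- as.vector(t(bead_masses(seq_v)))
  if (is.null(masses)) {
    masses <- ref_masses
  } else if (!isTRUE(all.equal(as.numeric(masses), ref_masses,
                               tolerance = 0))) {
    stop("masses do not match the model mass convention")
  }
  structure(list(sequence = sequence, ss = ss, coords = coords,
                 masses = as.numeric(masses)),
            class = "cg_protein")
}

#' Number of residues of a coarse-grained protein
#' @param protein a \code{cg_protein}.
#' @return integer residue count.
#' @export
n_residues <- function(protein) nchar(protein$sequence)

#' Flat bead index
#' @param res residue index (1-based).
#' @param bead bead index 1..4 (N, CA, C, SC) or bead name.
#' @return row index into the coordinate matrix.
#' @export
bead_index <- function(res, bead) {
  if (is.character(bead)) bead <- match(bead, BEAD_NAMES)
  (res - 1L) * 4L + bead
}

#' @export
print.cg_protein <- function(x, ...) {
  cat(sprintf("cg_protein: %d residues, %d beads\n  seq: %s\n  ss:  %s\n",
              n_residues(x), nrow(x$coords), x$sequence, x$ss))
  invisible(x)
}

# ---- PDB reading --------------------------------------------------------

#' Read a PDB chain into the coarse-grained representation
#'
#' Backbone beads take the N, CA and C atom positions; the SC bead is the
#' unweighted centroid of the residue's heavy sidechain atoms (an atom
#' named SC is accepted as a pre-collapsed sidechain). Glycine, which has
#' no heavy sidechain atoms, gets a pseudo-C-beta bead 1.53 Angstrom from
#' CA along the ideal tetrahedral direction. For alternate locations the
#' first altloc is kept; insertion codes are rejected.
#'
#' @param pdb_text PDB-format text (single string or character vector of
#'   lines).
#' @param chain_id chain identifier to extract.
#' @param ss optional secondary-structure string; defaults to all-coil.
#' @return a \code{cg_protein}.
#' @export
read_pdb_to_cg <- function(pdb_text, chain_id = "A", ss = NULL) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(if (length(pdb_text) == 1L && grepl("\n", pdb_text))
    strsplit(pdb_text, "\n")[[1]] else pdb_text, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$chain %in% chain_id, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain_id, "' not found")
  if (any(!is.na(at$insert))) stop("insertion codes are not supported")
  # first altloc only
  alt <- at$alt
  keep_alt <- is.na(alt) | alt == "" | alt == sort(unique(alt[!is.na(alt) & alt != ""]))[1]
  if (any(!is.na(alt) & alt != "")) at <- at[keep_alt, , drop = FALSE]
  # map residue names, reject non-standard
  resid <- at$resid
  mapped <- !is.na(NONSTANDARD_MAP[resid])
  resid[mapped] <- NONSTANDARD_MAP[resid[mapped]]
  unknown <- !(resid %in% AA3)
  if (any(unknown)) {
    stop("non-standard residue(s) without mapping: ",
         paste(unique(at$resid[unknown]), collapse = ", "))
  }
  at$resid <- resid
  resnos <- unique(at$resno)
  if (length(resnos) > 1L && any(diff(sort(resnos)) != 1L)) {
    stop("internal missing residues (gap in residue numbering)")
  }
  resnos <- sort(resnos)
  r <- length(resnos)
  coords <- matrix(NA_real_, 4L * r, 3L)
  seq_v <- character(r)
  backbone_set <- c("N", "CA", "C", "O", "OXT")
  for (idx in seq_len(r)) {
    rows <- at[at$resno == resnos[idx], , drop = FALSE]
    aa3 <- rows$resid[1]
    seq_v[idx] <- AA3_TO_1[[aa3]]
    for (b in 1:3) {
      hit <- which(rows$elety == BEAD_NAMES[b])
      if (length(hit) == 0L) {
        stop("missing backbone atom ", BEAD_NAMES[b],
             " at residue ", resnos[idx])
      }
      coords[bead_index(idx, b), ] <-
        as.numeric(rows[hit[1], c("x", "y", "z")])
    }
    sc_rows <- rows[!(rows$elety %in% backbone_set) &
                      !grepl("^\\d*H", rows$elety), , drop = FALSE]
    if (nrow(sc_rows) > 0L) {
      coords[bead_index(idx, 4L), ] <-
        colMeans(sc_rows[, c("x", "y", "z"), drop = FALSE])
    } else if (seq_v[idx] == "G") {
      npos <- coords[bead_index(idx, 1L), ]
      ca <- coords[bead_index(idx, 2L), ]
      cpos <- coords[bead_index(idx, 3L), ]
      coords[bead_index(idx, 4L), ] <-
        ca + IDEAL_GEOM$b_ca_cb * pseudo_cbeta_dir(npos, ca, cpos)
    } else {
      stop("no heavy sidechain atoms at residue ", resnos[idx])
    }
  }
  sequence <- paste(seq_v, collapse = "")
  if (is.null(ss)) ss <- strrep("C", r)
  cg_protein(sequence, ss, coords)
}

# ---- PSIPRED ss2 --------------------------------------------------------

#' Read a PSIPRED ss2 secondary-structure prediction
#'
#' Returns the per-residue argmax state over the three probability columns
#' (coil, helix, strand), as a string over H/E/C.
#'
#' @param ss2_text ss2-format text (string or lines).
#' @param sequence optional companion sequence; a length mismatch is an
#'   error.
#' @return secondary-structure string.
#' @export
read_ss2 <- function(ss2_text, sequence = NULL) {
  lines <- if (length(ss2_text) == 1L && grepl("\n", ss2_text))
    strsplit(ss2_text, "\n")[[1]] else ss2_text
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body) == 0L) stop("ss2 input has no data rows")
  states <- character(length(body))
  for (n in seq_along(body)) {
    f <- strsplit(trimws(lines[body[n]]), "\\s+")[[1]]
    if (length(f) < 6L || anyNA(suppressWarnings(as.numeric(f[4:6])))) {
      stop("malformed ss2 row at line ", body[n])
    }
    p <- as.numeric(f[4:6])  # coil, helix, strand
    states[n] <- c("C", "H", "E")[which.max(p)]
  }
  ss <- paste(states, collapse = "")
  if (!is.null(sequence) && nchar(sequence) != nchar(ss)) {
    stop("ss2 row count (", nchar(ss), ") does not match sequence length (",
         nchar(sequence), ")")
  }
  ss
}

# ---- peptide builder ----------------------------------------------------

#' Per-residue internal coordinates for the peptide builder
#'
#' @param phi,psi numeric vectors of backbone dihedrals in degrees (one per
#'   residue; phi of the first and psi of the last residue are unused).
#' @param omega peptide-bond dihedral(s) in degrees, recycled to the
#'   residue count; omega of residue i is the CA(i-1)-C(i-1)-N(i)-CA(i)
#'   dihedral (the first is unused).
#' @return an object of class \code{peptide_geometry}.
#' @export
peptide_geometry <- function(phi, psi, omega = 180) {
  r <- length(phi)
  if (length(psi) != r) stop("phi and psi lengths differ")
  omega <- rep_len(omega, r)
  structure(list(phi = wrap_angle(phi), psi = wrap_angle(psi),
                 omega = wrap_angle(omega), ideal = IDEAL_GEOM),
            class = "peptide_geometry")
}

#' Build a peptide from internal coordinates
#'
#' Backbone beads are chained by NeRF placement from idealised bond lengths
#' and angles (N-CA 1.46, CA-C 1.52, C-N 1.33 Angstrom; angles N-CA-C 111,
#' CA-C-N 116, C-N-CA 122 degrees) and the supplied phi/psi/omega. The SC
#' bead is placed along the pseudo-C-beta tetrahedral direction at an
#' idealised per-amino-acid CA-SC distance.
#'
#' @param sequence one-letter amino-acid string.
#' @param geometry a \code{peptide_geometry} whose vectors match the
#'   sequence length.
#' @param ss optional secondary-structure string (default all-coil).
#' @return a \code{cg_protein}.
#' @export
build_peptide <- function(sequence, geometry, ss = NULL) {
  seq_v <- strsplit(sequence, "")[[1]]
  r <- length(seq_v)
  if (r == 0L) stop("empty sequence")
  if (length(geometry$phi) != r) stop("geometry length != sequence length")
  g <- geometry$ideal
  coords <- matrix(NA_real_, 4L * r, 3L)
  coords[bead_index(1L, 1L), ] <- c(0, 0, 0)
  coords[bead_index(1L, 2L), ] <- c(g$b_n_ca, 0, 0)
  coords[bead_index(1L, 3L), ] <- coords[bead_index(1L, 2L), ] +
    g$b_ca_c * c(-cos(rad(g$a_n_ca_c)), sin(rad(g$a_n_ca_c)), 0)
  for (i in seq_len(r - 1L)) {
    ni <- coords[bead_index(i, 1L), ]
    cai <- coords[bead_index(i, 2L), ]
    ci <- coords[bead_index(i, 3L), ]
    n_next <- place_atom(ni, cai, ci, g$b_c_n, g$a_ca_c_n,
                         geometry$psi[i])
    ca_next <- place_atom(cai, ci, n_next, g$b_n_ca, g$a_c_n_ca,
                          geometry$omega[i + 1L])
    c_next <- place_atom(ci, n_next, ca_next, g$b_ca_c, g$a_n_ca_c,
                         geometry$phi[i + 1L])
    coords[bead_index(i + 1L, 1L), ] <- n_next
    coords[bead_index(i + 1L, 2L), ] <- ca_next
    coords[bead_index(i + 1L, 3L), ] <- c_next
  }
  for (i in seq_len(r)) {
    npos <- coords[bead_index(i, 1L), ]
    ca <- coords[bead_index(i, 2L), ]
    cpos <- coords[bead_index(i, 3L), ]
    coords[bead_index(i, 4L), ] <- ca +
      CA_SC_DIST[[seq_v[i]]] * pseudo_cbeta_dir(npos, ca, cpos)
  }
  if (is.null(ss)) ss <- strrep("C", r)
  cg_protein(sequence, ss, coords)
}

#' Recompute backbone dihedrals from coordinates
#'
#' @param protein a \code{cg_protein}.
#' @return list with numeric vectors \code{phi}, \code{psi}, \code{omega}
#'   (degrees; undefined terminal entries are NA).
#' @export
peptide_dihedrals <- function(protein) {
  x <- protein$coords
  r <- n_residues(protein)
  phi <- psi <- omega <- rep(NA_real_, r)
  for (i in seq_len(r)) {
    if (i > 1L) {
      phi[i] <- cg_dihedral(x[bead_index(i - 1L, 3L), ],
                            x[bead_index(i, 1L), ],
                            x[bead_index(i, 2L), ],
                            x[bead_index(i, 3L), ])
      omega[i] <- cg_dihedral(x[bead_index(i - 1L, 2L), ],
                              x[bead_index(i - 1L, 3L), ],
                              x[bead_index(i, 1L), ],
                              x[bead_index(i, 2L), ])
    }
    if (i < r) {
      psi[i] <- cg_dihedral(x[bead_index(i, 1L), ],
                            x[bead_index(i, 2L), ],
                            x[bead_index(i, 3L), ],
                            x[bead_index(i + 1L, 1L), ])
    }
  }
  list(phi = phi, psi = psi, omega = omega)
}

#' Build a starting conformation for folding runs
#'
#' In \code{predicted_ss} mode, residues predicted helical get
#' phi = -60, psi = -60 and strand/coil residues get phi = -120, psi = 140.
#' In \code{random_coil} mode each residue draws phi uniformly from
#' (-180, -30) and psi uniformly from (-180, 180) using the seeded
#' generator. Omega is 180 everywhere.
#'
#' @param sequence one-letter amino-acid string.
#' @param ss secondary-structure string of equal length.
#' @param mode "predicted_ss" or "random_coil".
#' @param rng_seed integer seed for random_coil draws.
#' @return a \code{cg_protein} carrying \code{ss}.
#' @export
build_start_conformation <- function(sequence, ss,
                                     mode = c("predicted_ss", "random_coil"),
                                     rng_seed = 1L) {
  mode <- match.arg(mode)
  r <- nchar(sequence)
  if (nchar(ss) != r) stop("sequence and ss lengths differ")
  ss_v <- strsplit(ss, "")[[1]]
  if (mode == "predicted_ss") {
    phi <- ifelse(ss_v == "H", -60, -120)
    psi <- ifelse(ss_v == "H", -60, 140)
  } else {
    draws <- with_seed(rng_seed, list(phi = stats::runif(r, -180, -30),
                                      psi = stats::runif(r, -180, 180)))
    phi <- draws$phi
    psi <- draws$psi
  }
  build_peptide(sequence, peptide_geometry(phi, psi, 180), ss = ss)
}

# ---- CG PDB writer ------------------------------------------------------

format_atom_line <- function(serial, name, resname, resno, xyz) {
  sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name, resname, resno, xyz[1], xyz[2], xyz[3])
}

cg_model_lines <- function(sequence, coords) {
  seq_v <- strsplit(sequence, "")[[1]]
  r <- length(seq_v)
  lines <- character(4L * r)
  for (i in seq_len(r)) {
    for (b in 1:4) {
      k <- bead_index(i, b)
      lines[k] <- format_atom_line(k, BEAD_NAMES[b], AA3[[seq_v[i]]], i,
                                   coords[k, ])
    }
  }
  lines
}

#' Write a coarse-grained protein or trajectory as PDB text
#'
#' One ATOM record per bead with atom names N, CA, C and SC; trajectory
#' snapshots become MODEL/ENDMDL blocks. Coordinates round-trip through
#' \code{read_pdb_to_cg} at the 3-decimal PDB precision.
#'
#' @param x a \code{cg_protein} or \code{cg_trajectory}.
#' @return character vector of PDB lines.
#' @export
write_cg_pdb <- function(x) {
  if (inherits(x, "cg_protein")) {
    c(cg_model_lines(x$sequence, x$coords), "END")
  } else if (inherits(x, "cg_trajectory")) {
    out <- character(0)
    for (s in seq_len(dim(x$coords)[1])) {
      out <- c(out, sprintf("MODEL     %4d", s),
               cg_model_lines(x$sequence, x$coords[s, , ]),
               "ENDMDL")
    }
    c(out, "END")
  } else {
    stop("x must be a cg_protein or cg_trajectory")
  }
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
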