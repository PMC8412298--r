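# The binned potential: bin specifications, table layout and indexing from
# (atom pair / angle / torsion, residue context) to table rows, energy
# lookup, interaction resolution and serialization.
#
# Components and table counts:
#   same     same-residue atom pairs, 6 pairs x 20 aa          = 120
#   close1-4 ordered atom-type pairs at residue separation 1-4 = 4 x 6400
#   general  unordered atom-type pairs, separation > 4         = 3240
#   angle    5 bond angles x 20 aa                             = 100
#   torsion  5 torsions x 20 aa x 3 ss states                  = 300
# Every table has 140 bins; torsion tables carry 2 extra learnable pad
# values used by the periodic force rule, giving 4,111,000 parameters.

PAIR_COMPONENTS <- c("same", "close1", "close2", "close3", "close4",
                     "general")

#' Bin specification
#'
#' @param lo,hi range covered by the 140 bins (Angstrom or degrees).
#' @param n_bins number of bins (always 140 in this model).
#' @param periodic_pad whether the stored table carries two extra pad
#'   values beyond the bins (torsions only).
#' @return a \code{bin_spec} list with the derived bin \code{width}.
#' @export
bin_spec <- function(lo, hi, n_bins = 140L, periodic_pad = FALSE) {
  stopifnot(hi > lo, n_bins > 0)
  structure(list(lo = lo, hi = hi, n_bins = as.integer(n_bins),
                 periodic_pad = periodic_pad,
                 width = (hi - lo) / n_bins),
            class = "bin_spec")
}

#' Bin centres of a bin specification
#' @param spec a \code{bin_spec}.
#' @return numeric vector of the \code{n_bins} bin centres.
#' @export
bin_centres <- function(spec) {
  spec$lo + (seq_len(spec$n_bins) - 0.5) * spec$width
}

default_bin_specs <- function() {
  list(same = bin_spec(0.7, 5.6),
       close1 = bin_spec(0.7, 14.7),
       close2 = bin_spec(0.7, 14.7),
       close3 = bin_spec(0.7, 14.7),
       close4 = bin_spec(0.7, 14.7),
       general = bin_spec(1, 15),
       angle = bin_spec(60, 180),
       torsion = bin_spec(-180, 180, periodic_pad = TRUE))
}

TABLE_COUNTS <- c(same = 120L, close1 = 6400L, close2 = 6400L,
                  close3 = 6400L, close4 = 6400L, general = 3240L,
                  angle = 100L, torsion = 300L)

#' Initialise a zeroed potential set
#'
#' All 29,360 tables exist with every energy value zero: 120 same-residue,
#' 4 x 6,400 close-residue and 3,240 general distance tables, 100 bond
#' angle tables and 300 torsion tables (the torsion tables hold 142 values
#' each: 140 bins plus 2 learnable pads for the periodic force rule).
#'
#' @return an object of class \code{potential_set}.
#' @export
init_potential_set <- function() {
  specs <- default_bin_specs()
  tables <- lapply(names(TABLE_COUNTS), function(nm) {
    ncols <- specs[[nm]]$n_bins + if (specs[[nm]]$periodic_pad) 2L else 0L
    matrix(0, TABLE_COUNTS[[nm]], ncols)
  })
  names(tables) <- names(TABLE_COUNTS)
  structure(list(tables = tables, specs = specs, version = 1L),
            class = "potential_set")
}

#' Count tables in a potential set
#' @param potential a \code{potential_set}.
#' @return integer number of individual potentials.
#' @export
n_tables <- function(potential) sum(vapply(potential$tables, nrow, 1L))

#' Count scalar learnable parameters in a potential set
#' @param potential a \code{potential_set}.
#' @return integer number of stored energy values.
#' @export
n_parameters <- function(potential) {
  sum(vapply(potential$tables, length, 1L))
}

#' @export
print.potential_set <- function(x, ...) {
  cat(sprintf("potential_set: %d tables, %d parameters\n",
              n_tables(x), n_parameters(x)))
  invisible(x)
}

# ---- bin lookup ---------------------------------------------------------

#' Find the occupied bin for a value
#'
#' Returns the 1-based index of the bin whose centre is nearest the value
#' (ties to the higher bin). For non-periodic specifications the result is
#' clamped to [2, n_bins - 1], so the first and last bins are never
#' occupied and out-of-range values map to the penultimate (or second)
#' bin. For the periodic torsion specification the value is wrapped and
#' all 140 bins are available; the pad values enter only through the force
#' rule across the +/-180 degree seam.
#'
#' @param value numeric vector of distances (Angstrom) or angles (degrees).
#' @param spec a \code{bin_spec}.
#' @return integer vector of bin indices.
#' @export
lookup_bin <- function(value, spec) {
  if (any(is.na(value))) stop("NaN/NA value in bin lookup")
  # the bin with the nearest centre is the bin whose interval contains the
  # value (a value exactly on a bin edge is equidistant and resolves to
  # the higher bin)
  if (spec$periodic_pad) {
    v <- (value - spec$lo) %% (spec$hi - spec$lo)
    k <- floor(v / spec$width) %% spec$n_bins
    as.integer(k) + 1L
  } else {
    k <- floor((value - spec$lo) / spec$width)
    as.integer(pmin(pmax(k, 1), spec$n_bins - 2L)) + 1L
  }
}

# ---- atom-type and table-row indexing -----------------------------------

#' Atom type index of a bead
#'
#' The 80 atom types are (amino acid, bead) combinations, indexed
#' (aa - 1) * 4 + bead with beads ordered N, CA, C, SC and amino acids in
#' the order ARNDCQEGHILKMFPSTWYV.
#'
#' @param aa one-letter amino-acid code(s).
#' @param bead bead name(s) ("N", "CA", "C", "SC") or index 1..4.
#' @return integer type index in 1..80.
#' @export
atom_type_index <- function(aa, bead) {
  if (is.character(bead)) bead <- match(bead, BEAD_NAMES)
  (match(aa, AA1) - 1L) * 4L + as.integer(bead)
}

#' General distance table row for an unordered type pair
#' @param t1,t2 atom type indices in 1..80 (order irrelevant).
#' @return row index in 1..3240.
#' @export
general_pair_row <- function(t1, t2) {
  a <- pmin(t1, t2)
  b <- pmax(t1, t2)
  as.integer((a - 1L) * 80L - (a - 1L) * a / 2L + b)
}

#' Close-residue distance table row for an ordered type pair
#' @param t_early type index of the earlier residue's atom.
#' @param t_late type index of the later residue's atom.
#' @return row index in 1..6400.
#' @export
close_pair_row <- function(t_early, t_late) {
  as.integer((t_early - 1L) * 80L + t_late)
}

# same-residue bead pairs in canonical order
SAME_PAIRS <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                    c(2L, 3L), c(2L, 4L), c(3L, 4L))

#' Same-residue distance table row
#' @param aa one-letter amino-acid code(s).
#' @param b1,b2 bead indices 1..4 or names (order irrelevant).
#' @return row index in 1..120.
#' @export
same_pair_row <- function(aa, b1, b2) {
  if (is.character(b1)) b1 <- match(b1, BEAD_NAMES)
  if (is.character(b2)) b2 <- match(b2, BEAD_NAMES)
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  pair_id <- match(paste(lo, hi), paste(SAME_PAIRS[, 1], SAME_PAIRS[, 2]))
  as.integer((match(aa, AA1) - 1L) * 6L + pair_id)
}

#' Bond-angle table row
#' @param aa one-letter amino-acid code(s).
#' @param angle_id angle identifier 1..5: 1 N-CA-C, 2 CA-C-N(+1),
#'   3 C(-1)-N-CA, 4 N-CA-SC, 5 C-CA-SC.
#' @return row index in 1..100.
#' @export
angle_row_index <- function(aa, angle_id) {
  as.integer((match(aa, AA1) - 1L) * 5L + angle_id)
}

#' Torsion table row
#' @param aa one-letter amino-acid code(s).
#' @param torsion_id torsion identifier 1..5: 1 phi, 2 psi, 3 omega,
#'   4 C(-1)-N-CA-SC, 5 SC-CA-C-N(+1).
#' @param ss secondary-structure state(s) "H", "E" or "C".
#' @return row index in 1..300.
#' @export
torsion_row_index <- function(aa, torsion_id, ss) {
  ssi <- match(ss, SS_STATES)
  as.integer(((ssi - 1L) * 20L + match(aa, AA1) - 1L) * 5L + torsion_id)
}

# ---- interaction resolution ---------------------------------------------

#' Resolve the interaction list of a protein
#'
#' Maps every bead pair to exactly one distance table (same-residue for
#' separation 0, ordered close-residue tables for separations 1-4,
#' unordered general tables beyond) and enumerates the bond-angle and
#' torsion terms; terms referencing nonexistent terminal neighbours are
#' omitted. Each angle/torsion is assigned to the amino acid (and, for
#' torsions, the secondary-structure state) of the residue owning the CA
#' pivot.
#'
#' @param protein a \code{cg_protein}.
#' @return a list with elements \code{pairs}, \code{angles} and
#'   \code{torsions}, each holding parallel index vectors (bead rows,
#'   component names and table rows).
#' @export
resolve_interactions <- function(protein) {
  seq_v <- strsplit(protein$sequence, "")[[1]]
  ss_v <- strsplit(protein$ss, "")[[1]]
  r <- length(seq_v)
  nb <- 4L * r
  res_of <- rep(seq_len(r), each = 4L)
  bead_of <- rep(1:4, r)
  type_of <- atom_type_index(seq_v[res_of], bead_of)

  idx <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
  p <- idx[, 1]; q <- idx[, 2]           # p < q, so res_of[p] <= res_of[q]
  sep <- res_of[q] - res_of[p]
  comp <- ifelse(sep == 0L, "same",
                 ifelse(sep <= 4L, paste0("close", sep), "general"))
  row <- integer(length(p))
  s0 <- sep == 0L
  row[s0] <- same_pair_row(seq_v[res_of[p[s0]]], bead_of[p[s0]],
                           bead_of[q[s0]])
  sc <- sep >= 1L & sep <= 4L
  row[sc] <- close_pair_row(type_of[p[sc]], type_of[q[sc]])
  sg <- sep > 4L
  row[sg] <- general_pair_row(type_of[p[sg]], type_of[q[sg]])
  pairs <- list(i = p, j = q, comp = comp, row = row)

  bi <- function(res, bead) bead_index(res, bead)
  ai <- aj <- ak <- arow <- integer(0)
  ti <- tj <- tk <- tl <- trow <- integer(0)
  for (i in seq_len(r)) {
    aa <- seq_v[i]; ss <- ss_v[i]
    add_angle <- function(x, y, z, id) {
      ai <<- c(ai, x); aj <<- c(aj, y); ak <<- c(ak, z)
      arow <<- c(arow, angle_row_index(aa, id))
    }
    add_tor <- function(w, x, y, z, id) {
      ti <<- c(ti, w); tj <<- c(tj, x); tk <<- c(tk, y); tl <<- c(tl, z)
      trow <<- c(trow, torsion_row_index(aa, id, ss))
    }
    add_angle(bi(i, 1L), bi(i, 2L), bi(i, 3L), 1L)
    if (i < r) add_angle(bi(i, 2L), bi(i, 3L), bi(i + 1L, 1L), 2L)
    if (i > 1L) add_angle(bi(i - 1L, 3L), bi(i, 1L), bi(i, 2L), 3L)
    add_angle(bi(i, 1L), bi(i, 2L), bi(i, 4L), 4L)
    add_angle(bi(i, 3L), bi(i, 2L), bi(i, 4L), 5L)
    if (i > 1L) {
      add_tor(bi(i - 1L, 3L), bi(i, 1L), bi(i, 2L), bi(i, 3L), 1L)
      add_tor(bi(i - 1L, 2L), bi(i - 1L, 3L), bi(i, 1L), bi(i, 2L), 3L)
      add_tor(bi(i - 1L, 3L), bi(i, 1L), bi(i, 2L), bi(i, 4L), 4L)
    }
    if (i < r) {
      add_tor(bi(i, 1L), bi(i, 2L), bi(i, 3L), bi(i + 1L, 1L), 2L)
      add_tor(bi(i, 4L), bi(i, 2L), bi(i, 3L), bi(i + 1L, 1L), 5L)
    }
  }
  list(pairs = pairs,
       angles = list(i = ai, j = aj, k = ak, row = arow),
       torsions = list(i = ti, j = tj, k = tk, l = tl, row = trow))
}

# ---- energy -------------------------------------------------------------

# Occupied-bin table columns and rows for every term of a system at
# coordinates X; used by both the energy and the force path.
occupied_bins <- function(X, sys, specs) {
  p <- sys$pairs
  d <- geom_distances(X, p$i, p$j)
  pair_bin <- integer(length(d))
  for (cm in PAIR_COMPONENTS) {
    sel <- sys$pair_comp_idx[[cm]]
    if (length(sel)) pair_bin[sel] <- lookup_bin(d[sel], specs[[cm]])
  }
  ang <- geom_angles(X, sys$angles$i, sys$angles$j, sys$angles$k)
  tor <- geom_dihedrals(X, sys$torsions$i, sys$torsions$j, sys$torsions$k,
                        sys$torsions$l)
  list(pair_bin = pair_bin,
       angle_bin = lookup_bin(ang, specs$angle),
       torsion_bin = lookup_bin(tor, specs$torsion))
}

#' Total potential energy of a conformation
#'
#' Sum over all resolved interaction terms of the stored energy at each
#' term's occupied bin; torsion tables are selected by the residue's
#' secondary-structure state. Invariant under rigid-body motion.
#'
#' @param protein a \code{cg_protein}.
#' @param potential a \code{potential_set}.
#' @return total energy (unitless).
#' @export
total_energy <- function(protein, potential) {
  sys <- cg_system(protein, potential)
  system_energy(protein$coords, sys, potential$tables)
}

system_energy <- function(X, sys, tables) {
  ob <- occupied_bins(X, sys, sys$specs)
  e <- 0
  for (cm in PAIR_COMPONENTS) {
    sel <- sys$pair_comp_idx[[cm]]
    if (length(sel)) {
      m <- tables[[cm]]
      e <- e + sum(m[sys$pairs$row[sel] +
                       (ob$pair_bin[sel] - 1L) * nrow(m)])
    }
  }
  if (length(sys$angles$row)) {
    m <- tables$angle
    e <- e + sum(m[sys$angles$row + (ob$angle_bin - 1L) * nrow(m)])
  }
  if (length(sys$torsions$row)) {
    m <- tables$torsion
    e <- e + sum(m[sys$torsions$row + ob$torsion_bin * nrow(m)])
  }
  e
}

# ---- serialization ------------------------------------------------------

#' Save a potential set
#'
#' Versioned container (RDS) holding the format tag, version, bin
#' specifications and all tables; the round trip is lossless.
#'
#' @param potential a \code{potential_set}.
#' @param path file path.
#' @return invisibly, \code{path}.
#' @export
save_potential <- function(potential, path) {
  stopifnot(inherits(potential, "potential_set"))
  saveRDS(list(format = "cglearn_potential_set",
               version = potential$version,
               specs = potential$specs,
               tables = potential$tables), path)
  invisible(path)
}

#' Load a potential set
#' @param path file path written by \code{save_potential}.
#' @return a \code{potential_set}.
#' @export
load_potential <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read potential file: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "cglearn_potential_set")) {
    stop("not a cglearn potential file")
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported potential file version: ", obj$version)
  }
  if (!identical(sort(names(obj$tables)), sort(names(TABLE_COUNTS))) ||
      !all(vapply(names(TABLE_COUNTS),
                  function(nm) nrow(obj$tables[[nm]]) == TABLE_COUNTS[[nm]],
                  TRUE))) {
    stop("potential file has wrong table layout")
  }
  structure(list(tables = obj$tables, specs = obj$specs,
                 version = obj$version),
            class = "potential_set")
}
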