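# Deterministic synthetic fixtures: mini-proteins built from idealised
# internal coordinates and toy potentials with known minima, so the whole
# pipeline (including scaled-down training) is testable offline.

MINI_PROTEIN_AA <- c(H = "AELKA", E = "VTIVT", C = "GSNPG")

#' Build a synthetic mini-protein
#'
#' Constructs a native-like coarse-grained structure from idealised
#' phi/psi values per secondary-structure state (helix -57/-47, strand
#' -130/135, coil -80/130) with small seeded jitter (sd 3 degrees for
#' H/E, 10 for coil), via the internal peptide builder. The sequence
#' cycles through a small state-typical amino-acid pool.
#'
#' @param n_residues number of residues (3 to 30).
#' @param ss_pattern secondary-structure string, recycled to
#'   \code{n_residues}.
#' @param rng_seed integer seed; identical inputs give identical output.
#' @return a \code{cg_protein}.
#' @export
make_mini_protein <- function(n_residues, ss_pattern = "H", rng_seed = 1L) {
  if (n_residues < 3L || n_residues > 30L) {
    stop("n_residues must be between 3 and 30")
  }
  ss_v <- rep_len(strsplit(ss_pattern, "")[[1]], n_residues)
  if (!all(ss_v %in% SS_STATES)) stop("ss_pattern must be over H/E/C")
  ideal <- list(H = c(-57, -47), E = c(-130, 135), C = c(-80, 130))
  jitter_sd <- c(H = 3, E = 3, C = 10)
  seq_v <- character(n_residues)
  counters <- c(H = 0L, E = 0L, C = 0L)
  for (i in seq_len(n_residues)) {
    pool <- MINI_PROTEIN_AA[[ss_v[i]]]
    counters[ss_v[i]] <- counters[ss_v[i]] + 1L
    k <- (counters[ss_v[i]] - 1L) %% nchar(pool) + 1L
    seq_v[i] <- substr(pool, k, k)
  }
  angles <- with_seed(rng_seed, {
    phi <- psi <- numeric(n_residues)
    for (i in seq_len(n_residues)) {
      base <- ideal[[ss_v[i]]]
      phi[i] <- base[1] + stats::rnorm(1, 0, jitter_sd[[ss_v[i]]])
      psi[i] <- base[2] + stats::rnorm(1, 0, jitter_sd[[ss_v[i]]])
    }
    list(phi = phi, psi = psi)
  })
  build_peptide(paste(seq_v, collapse = ""),
                peptide_geometry(angles$phi, angles$psi, 180),
                ss = paste(ss_v, collapse = ""))
}

#' One entry of a toy potential specification
#'
#' @param component table component name: "same", "close1".."close4",
#'   "general", "angle" or "torsion".
#' @param row table row index within the component.
#' @param form functional form: "harmonic" (k/2 (x - x0)^2 + offset) or
#'   "values" (explicit per-bin values).
#' @param x0 location of the harmonic minimum (Angstrom or degrees).
#' @param k harmonic force constant.
#' @param offset constant added to the form (a negative offset plants a
#'   well of known depth).
#' @param values explicit values for form = "values" (length 140, or 142
#'   for a torsion table).
#' @return a toy-potential entry list.
#' @export
toy_entry <- function(component, row, form = c("harmonic", "values"),
                      x0 = NULL, k = 1, offset = 0, values = NULL) {
  form <- match.arg(form)
  list(component = component, row = row, form = form, x0 = x0, k = k,
       offset = offset, values = values)
}

#' Build a toy potential from sampled functional forms
#'
#' Each entry's form is evaluated at the component's bin centres (torsion
#' pads take the two pseudo-centres half a bin beyond the range) and
#' written into the named table row; all other tables stay zero, so
#' disjoint entries add independently.
#'
#' @param spec list of \code{\link{toy_entry}} entries (empty list gives
#'   the zero-initialised set).
#' @return a \code{potential_set}.
#' @export
make_toy_potential <- function(spec = list()) {
  pot <- init_potential_set()
  for (entry in spec) {
    cm <- entry$component
    if (is.null(pot$tables[[cm]])) stop("unknown component: ", cm)
    m <- pot$tables[[cm]]
    if (is.null(entry$row) || entry$row < 1L || entry$row > nrow(m)) {
      stop("unknown row selector for component ", cm)
    }
    sp <- pot$specs[[cm]]
    x <- bin_centres(sp)
    if (sp$periodic_pad) {
      x <- c(sp$lo - sp$width / 2, x, sp$hi + sp$width / 2)
    }
    vals <- switch(entry$form,
      harmonic = entry$k / 2 * (x - entry$x0)^2 + entry$offset,
      values = {
        if (length(entry$values) != ncol(m)) {
          stop("values length must be ", ncol(m), " for component ", cm)
        }
        entry$values
      })
    pot$tables[[cm]][entry$row, ] <- pot$tables[[cm]][entry$row, ] + vals
  }
  pot
}

#' Standard fixture set for scaled-down training
#'
#' Five mixed-topology mini-proteins (helix, strand, coil and mixed
#' patterns, 6 to 12 residues) built deterministically from a seed.
#'
#' @param rng_seed integer seed.
#' @return list of five \code{cg_protein}.
#' @export
make_training_fixtures <- function(rng_seed = 1L) {
  list(make_mini_protein(8L, "H", rng_seed),
       make_mini_protein(6L, "E", rng_seed + 1L),
       make_mini_protein(10L, "HHHHCCEEEE", rng_seed + 2L),
       make_mini_protein(7L, "C", rng_seed + 3L),
       make_mini_protein(12L, "HHHHHHCCCHHH", rng_seed + 4L))
}
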