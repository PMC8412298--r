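# Model-wide constants: amino-acid alphabet, bead definitions, masses,
# idealised builder geometry and background composition.

#' Amino-acid and bead constants
#'
#' The model represents each residue by four beads in fixed order
#' N, CA (C-alpha), C (carbonyl carbon) and SC (sidechain centroid).
#' Model masses are unitless: 15 for N (amide H folded in), 13 for CA,
#' 28 for C (carbonyl O folded in); the SC mass is the summed heavy-atom
#' mass of the all-atom sidechain, except glycine which is set to 10.
#'
#' @name cg_constants
#' @keywords internal
NULL

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA3_TO_1 <- stats::setNames(names(AA3), AA3)

# Residue-name mapping applied before rejecting non-standard residues.
NONSTANDARD_MAP <- c(MSE = "MET", SEC = "CYS", MLY = "LYS", HYP = "PRO")

BEAD_NAMES <- c("N", "CA", "C", "SC")
N_BEADS_PER_RES <- 4L

BACKBONE_MASSES <- c(N = 15, CA = 13, C = 28)

# Summed heavy-atom masses (C=12, N=14, O=16, S=32) of the sidechain;
# glycine is set artificially heavier at 10 so its pseudo-bead has inertia.
SC_MASSES <- c(
  A = 12,  R = 90,  N = 54,  D = 56,  C = 44,
  Q = 66,  E = 68,  G = 10,  H = 76,  I = 48,
  L = 48,  K = 62,  M = 68,  F = 84,  P = 36,
  S = 28,  T = 40,  W = 122, Y = 100, V = 36
)

# Idealised backbone geometry for the internal peptide builder
# (Engh-Huber-like values; bond lengths in Angstrom, angles in degrees).
IDEAL_GEOM <- list(
  b_n_ca = 1.46, b_ca_c = 1.52, b_c_n = 1.33,
  a_n_ca_c = 111, a_ca_c_n = 116, a_c_n_ca = 122,
  b_ca_cb = 1.53, a_tetrahedral = 109.5
)

# Idealised C-alpha to sidechain-centroid distances (Angstrom) used by the
# peptide builder; rough centroid distances for each sidechain. Glycine uses
# the pseudo-C-beta distance.
CA_SC_DIST <- c(
  A = 1.53, R = 4.10, N = 2.50, D = 2.50, C = 2.30,
  Q = 3.10, E = 3.10, G = 1.53, H = 3.10, I = 2.30,
  L = 2.60, K = 3.50, M = 3.20, F = 3.40, P = 1.90,
  S = 1.90, T = 1.90, W = 3.90, Y = 3.80, V = 2.00
)

# Background amino-acid frequencies (approximate PDB composition; leucine
# 9.6%, tryptophan 1.2%). Normalised to sum to one on load.
AA_BACKGROUND <- local({
  f <- c(A = 8.3, R = 5.1, N = 4.2, D = 5.8, C = 1.4,
         Q = 3.7, E = 6.7, G = 7.4, H = 2.4, I = 5.7,
         L = 9.6, K = 5.9, M = 2.2, F = 4.0, P = 4.6,
         S = 6.1, T = 5.5, W = 1.2, Y = 3.4, V = 6.9)
  f / sum(f)
})

SS_STATES <- c("H", "E", "C")

#' Per-amino-acid bead masses
#'
#' Returns the four model masses (N, CA, C, SC) for a one-letter amino-acid
#' code.
#'
#' @param aa character vector of one-letter amino-acid codes.
#' @return numeric matrix with one row per input and columns N, CA, C, SC.
#' @examples
#' bead_masses("G")
#' @export
bead_masses <- function(aa) {
  stopifnot(all(aa %in% AA1))
  m <- cbind(N = rep(BACKBONE_MASSES[["N"]], length(aa)),
             CA = BACKBONE_MASSES[["CA"]],
             C = BACKBONE_MASSES[["C"]],
             SC = SC_MASSES[aa])
  rownames(m) <- aa
  m
}
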