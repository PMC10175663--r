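# Amino-acid constants used across the package. All values are standard
# published scales (Kyte-Doolittle hydropathy, atomic masses, van der Waals
# radii); side-chain atom counts are heavy atoms beyond C-beta.

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# Kyte & Doolittle hydropathy, range [-4.5, 4.5]
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Heavy side-chain atoms beyond CB (GLY has no CB at all)
AA_SIDECHAIN_EXTRA <- c(A = 0, R = 6, N = 3, D = 3, C = 1, Q = 4, E = 4,
                        G = 0, H = 5, I = 3, L = 3, K = 4, M = 3, F = 6,
                        P = 2, S = 1, T = 2, W = 9, Y = 7, V = 2)

# Atomic masses (u) and van der Waals radii (Angstrom) for elements seen in
# protein heavy atoms; H included for completeness.
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974)
ELEMENT_VDW <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# Fixed per-residue formal charge scheme for the screened-Coulomb
# electrostatics backend: charge is distributed over the named side-chain
# heavy atoms when present, else over the outermost side-chain atom.
RESIDUE_CHARGE <- list(
  D = list(q = -1, atoms = c("OD1", "OD2")),
  E = list(q = -1, atoms = c("OE1", "OE2")),
  K = list(q = +1, atoms = "NZ"),
  R = list(q = +1, atoms = c("NE", "NH1", "NH2")),
  H = list(q = +0.1, atoms = c("ND1", "NE2"))
)

# Hydrogen-bond donor / acceptor heavy atoms by PDB atom name. Backbone N is
# a donor and backbone O an acceptor for every residue; hydroxyls are both.
HBOND_DONORS <- list(
  all = "N",
  R = c("NE", "NH1", "NH2"), K = "NZ", W = "NE1", H = c("ND1", "NE2"),
  N = "ND2", Q = "NE2", S = "OG", T = "OG1", Y = "OH"
)
HBOND_ACCEPTORS <- list(
  all = "O",
  D = c("OD1", "OD2"), E = c("OE1", "OE2"), N = "OD1", Q = "OE1",
  S = "OG", T = "OG1", Y = "OH", H = c("ND1", "NE2"), M = "SD"
)

element_of_atom <- function(atom_name) {
  nm <- toupper(sub("^[0-9]*", "", trimws(atom_name)))
  el <- substr(nm, 1, 1)
  ifelse(el %in% names(ELEMENT_VDW), el, "C")
}

#' Canonical BLOSUM62 substitution matrix
#'
#' The 20 x 20 standard-residue block of the BLOSUM62 log-odds substitution
#' matrix, taken from the table shipped with Biostrings.
#'
#' @return A symmetric 20 x 20 integer matrix with standard one-letter
#'   amino-acid row and column names.
#' @export
#' @examples
#' blosum62()["A", "A"]
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_STANDARD, AA_STANDARD]
  storage.mode(m) <- "double"
  m
}

#' Synthetic PMBEC-style substitution matrix
#'
#' A synthetic surrogate for the PMBEC amino-acid similarity matrix (a
#' covariance-derived matrix from peptide-MHC binding energies). The
#' published PMBEC table is not redistributed here; this surrogate has the
#' same structure -- symmetric, unit diagonal, values in \[-1, 1\],
#' correlation-type similarity between residues -- and is computed as the
#' Pearson correlation between BLOSUM62 substitution profiles. Supply the
#' published table via [read_substitution_matrix()] to reproduce it exactly.
#'
#' @return A symmetric 20 x 20 numeric matrix, unit diagonal.
#' @export
pmbec_surrogate <- function() {
  m <- stats::cor(blosum62())
  (m + t(m)) / 2
}

#' Read a substitution matrix from CSV
#'
#' Reads a 20 x 20 amino-acid substitution matrix (e.g. the published PMBEC
#' table) from a CSV file whose first column and header row are one-letter
#' residue codes.
#'
#' @param path Path to a CSV file.
#' @return A symmetric 20 x 20 numeric matrix ordered by [AA_STANDARD]
#'   convention.
#' @export
read_substitution_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  missing <- setdiff(AA_STANDARD, rownames(m))
  if (length(missing) > 0) {
    stop("substitution matrix is missing residues: ",
         paste(missing, collapse = ", "))
  }
  m <- m[AA_STANDARD, AA_STANDARD]
  if (max(abs(m - t(m))) > 1e-8) stop("substitution matrix is not symmetric")
  (m + t(m)) / 2
}

check_standard_residues <- function(seq_string, what = "peptide") {
  letters1 <- strsplit(seq_string, "")[[1]]
  bad <- setdiff(unique(letters1), AA_STANDARD)
  if (length(bad) > 0) {
    stop(sprintf("%s '%s' contains nonstandard residue letter(s): %s",
                 what, seq_string, paste(bad, collapse = ", ")))
  }
  invisible(letters1)
}
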