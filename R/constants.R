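# Unit conventions: files carry coordinates in angstrom; all physics runs in
# atomic units (bohr, hartree); energies are reported in kcal/mol.
BOHR_ANGSTROM <- 0.52917721
HARTREE_KCAL <- 627.509474

#' Atom type labels
#'
#' The closed enumeration of atom types used by the component energy models:
#' hydrogens typed by their bonding partner (`HC`, `HN`, `HO`), carbons by
#' coordination number (`C4`, `C3`, `C2`), trivalent nitrogen (`N3`), and
#' one- or two-coordinate oxygen (`O1`, `O2`).
#'
#' @return Character vector of the nine atom type labels.
#' @export
atom_type_labels <- function() {
  c("HC", "HN", "HO", "C4", "C3", "C2", "N3", "O1", "O2")
}

ELEMENTS <- c("H", "C", "N", "O")

# Pyykko-style single-bond covalent radii, angstrom
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)

ATOMIC_NUMBER <- c(H = 1, C = 6, N = 7, O = 8)
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)

# Free-atom reference data (atomic units). alpha/C6 are the standard
# Tkatchenko-Scheffler free-atom values; radial moments and valence widths are
# representative magnitudes for the synthetic property generator.
FREE_ATOM <- data.frame(
  element    = c("H", "C", "N", "O"),
  alpha_free = c(4.50, 12.00, 7.40, 5.40),
  c6_free    = c(6.50, 46.60, 24.20, 15.60),
  r2         = c(3.00, 13.00, 10.50, 8.50),
  r4         = c(22.50, 90.00, 60.00, 42.00),
  sigma      = c(0.35, 0.50, 0.45, 0.40),
  hirshfeld  = c(0.65, 0.95, 0.97, 0.98),
  stringsAsFactors = FALSE
)

# Representative atomic partial charges by atom type, used by the synthetic
# property generator (renormalized to neutrality per monomer).
TYPE_CHARGE <- c(
  HC = 0.06, HN = 0.36, HO = 0.42,
  C4 = -0.24, C3 = 0.20, C2 = -0.06,
  N3 = -0.72, O1 = -0.46, O2 = -0.60
)
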