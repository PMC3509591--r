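# Physical constants and amino-acid bookkeeping shared across modules.
# Units throughout: nm, kJ/mol, amu, ps, elementary charge e.
# Angles are stored in radians internally and exposed in degrees.

#' @keywords internal
KB <- 0.0083145          # Boltzmann constant, kJ mol^-1 K^-1

#' @keywords internal
KE_COULOMB <- 138.935    # 1/(4 pi eps0), kJ mol^-1 nm e^-2

# Residues represented by a single backbone bead B_<res>; all others get a
# uniform B_GLY backbone bead plus a distinct side-chain bead S_<res>.
ONE_BEAD_RESIDUES <- c("ALA", "ASN", "ASP", "CYS", "GLY",
                       "LEU", "PRO", "SER", "THR", "VAL")
TWO_BEAD_RESIDUES <- c("ARG", "GLN", "GLU", "HIS", "ILE",
                       "LYS", "MET", "PHE", "TRP", "TYR")
STANDARD_RESIDUES <- c(ONE_BEAD_RESIDUES, TWO_BEAD_RESIDUES)

WATER_RESIDUES <- c("HOH", "SOL", "WAT")

# Average in-chain residue masses (amu), hydrogens included.
RESIDUE_MASS <- c(
  ALA =  71.0788, ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLN = 128.1307, GLU = 129.1155, GLY =  57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO =  97.1167, SER =  87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL =  99.1326)

# Mass of the N-H-CA-HA-C-O backbone moiety; the side-chain bead of a
# two-bead residue carries the remainder (side-chain heavy atoms + their H).
BACKBONE_MOIETY_MASS <- 56.044

WATER_MOLECULE_MASS <- 18.0153
WATER_BEAD_SIZE <- 5L
WATER_BEAD_MASS <- WATER_BEAD_SIZE * WATER_MOLECULE_MASS  # ~90 amu

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, SE = 78.971)

# Equilibrium backbone-to-side-chain bond lengths (nm), one per side-chain
# bead type.
BS_BOND_LENGTH <- c(
  ARG = 0.406, GLN = 0.301, GLU = 0.295, HIS = 0.307, ILE = 0.226,
  LYS = 0.344, MET = 0.287, PHE = 0.333, TRP = 0.381, TYR = 0.371)

BB_BOND_LENGTH <- 0.38      # nm, consecutive backbone beads
BB_BOND_K      <- 1e5       # kJ nm^-2 mol^-1
BS_BOND_K      <- 5e3       # kJ nm^-2 mol^-1

# Lennard-Jones zero-crossing distances c_ii (nm) for homo pairs.
LJ_ZERO_CROSSING <- c(
  B_ALA = 0.50, B_ASN = 0.60, B_ASP = 0.55, B_CYS = 0.50, B_GLY = 0.40,
  B_LEU = 0.55, B_PRO = 0.65, B_SER = 0.50, B_THR = 0.50, B_VAL = 0.50,
  S_ARG = 0.60, S_GLN = 0.45, S_GLU = 0.45, S_HIS = 0.45, S_ILE = 0.50,
  S_LYS = 0.45, S_MET = 0.45, S_PHE = 0.45, S_TRP = 0.65, S_TYR = 0.55,
  W     = 0.51)

WATER_EPSILON <- 6.0        # kJ/mol, CG water bead well depth

# Integer charges (e); all other beads are neutral.
BEAD_CHARGE_TABLE <- c(B_ASP = -1, S_GLU = -1, S_ARG = 1, S_LYS = 1)

one_letter_to_three <- function(seq1) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  codes <- strsplit(toupper(seq1), "")[[1]]
  bad <- setdiff(codes, names(map))
  if (length(bad))
    stop("unknown one-letter residue code(s): ", paste(unique(bad), collapse = ", "))
  unname(map[codes])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap an angle (radians) into (-pi, pi].
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}
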