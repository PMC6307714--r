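# Canonical amino-acid tables and ideal backbone geometry constants.

#' The twenty canonical amino acids
#'
#' One-letter codes in the standard three-letter-alphabetical order used for
#' all parameter indexing in the package.
#' @export
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# Backbone interaction sites, in the fixed ordering used for parameter
# indexing (amide proton, carbonyl oxygen, amide nitrogen, C-alpha, carbonyl
# carbon).
BB_SITES <- c("H", "O", "N", "CA", "C")

# Ideal backbone covalent geometry (Angstrom, degrees -> radians below).
GEOM <- list(
  b_n_ca  = 1.458,
  b_ca_c  = 1.525,
  b_c_n   = 1.329,
  b_c_o   = 1.231,
  b_n_h   = 1.010,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.2 * pi / 180,
  a_ca_c_n = 116.2 * pi / 180,
  a_c_n_ca = 121.7 * pi / 180,
  a_n_ca_cb = acos(-1 / 3),   # ideal tetrahedral
  omega = pi
)

# Default burial-count geometry: logistic radial switch and hemispherical
# angular switch along the C-alpha -> C-beta direction.
BURIAL_DEFAULTS <- list(r_center = 7.0, r_width = 1.0,
                        a_center = 0.0, a_width = 0.2)

# Fixed (non-trainable) steric constants: quadratic repulsion
# eps * (1 - r/r_cut)^2 among non-bonded backbone N, CA, CB, C atoms.
STERIC_DEFAULTS <- list(eps = 20.0, r_cut = 3.2, min_seq_sep = 2L)

# Fixed hydrogen-bond geometry (only the magnitude is trainable).  The
# switching constants are calibrated so that the canonical alpha-helix
# (phi, psi) = (-57, -47) donor/acceptor geometry lies on the favorable
# plateau of every switch; see the methods vignette.
HBOND_GEOM <- list(dist_center = 2.4, dist_width = 0.6,
                   don_center = 0.55, don_width = 0.35,
                   acc_center = 0.45, acc_width = 0.40,
                   min_seq_sep = 2L)

# Display-unit conversions (used only for reporting): one model energy unit
# is 0.6 kcal/mol and model temperature T = 1 corresponds to 300 K.
UNITS <- list(energy_kcal = 0.6, t_unit_kelvin = 300)
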