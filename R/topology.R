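#' Backbone state: the dynamical degrees of freedom
#'
#' Only the N, C-alpha and C atoms of each residue undergo dynamics.  A
#' `cg_backbone` holds the sequence, the positions of those atoms (a
#' `3*nres` by 3 matrix, rows ordered N, CA, C per residue, Angstrom) and
#' matching momenta.  All other atoms (O, H, C-beta, side-chain beads) are
#' derived quantities computed at every force evaluation.
#'
#' @name cg_backbone
NULL

new_backbone <- function(sequence, positions, momenta = NULL) {
  n <- length(sequence)
  stopifnot(nrow(positions) == 3 * n, ncol(positions) == 3)
  if (is.null(momenta)) momenta <- matrix(0, 3 * n, 3)
  structure(list(seq = sequence, x = positions, p = momenta, nres = n),
            class = "cg_backbone")
}

#' Row index of a backbone atom
#' @param i residue index (1-based), possibly a vector.
#' @param atom one of "N", "CA", "C".
#' @keywords internal
atom_row <- function(i, atom) {
  off <- match(atom, c("N", "CA", "C"))
  (i - 1L) * 3L + off
}

check_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  if (all(nchar(sequence) == 3)) sequence <- unname(AA_ONE[sequence])
  if (length(sequence) < 2)
    cg_error("cg_sequence_error", "sequence must have at least 2 residues")
  bad <- which(!(sequence %in% AA_CODES) | is.na(sequence))
  if (length(bad))
    cg_error("cg_sequence_error",
             sprintf("unknown residue code at position %d", bad[1]))
  sequence
}

#' Build a backbone topology from raw atom records
#'
#' Assembles a [cg_backbone] from per-atom records, checking that every
#' residue has its three backbone atoms and that the chain is unbroken.
#'
#' @param sequence character vector of residue codes (1- or 3-letter).
#' @param coords data frame with columns `res` (1-based residue index),
#'   `atom` ("N", "CA" or "C"), and `x`, `y`, `z` (Angstrom).
#' @param validate check bonded distances against ideal values (+/- 20%).
#' @return a [cg_backbone].
#' @export
build_topology <- function(sequence, coords, validate = TRUE) {
  sequence <- check_sequence(sequence)
  n <- length(sequence)
  x <- matrix(NA_real_, 3 * n, 3)
  for (i in seq_len(n)) {
    for (atom in c("N", "CA", "C")) {
      sel <- coords$res == i & coords$atom == atom
      if (sum(sel) != 1)
        cg_error("cg_missing_atom_error",
                 sprintf("missing backbone atom %s in residue %d", atom, i),
                 residue = i, atom = atom)
      x[atom_row(i, atom), ] <- as.numeric(coords[sel, c("x", "y", "z")])
    }
  }
  if (any(!is.finite(x)))
    cg_error("cg_missing_atom_error", "non-finite backbone coordinates")
  st <- new_backbone(sequence, x)
  if (n > 1) {
    dcn <- sqrt(rowSums((x[atom_row(2:n, "N"), , drop = FALSE] -
                         x[atom_row(1:(n - 1), "C"), , drop = FALSE])^2))
    brk <- which(dcn > 2.0)
    if (length(brk))
      cg_error("cg_chain_break_error",
               sprintf("chain break between residues %d and %d (C-N %.2f A)",
                       brk[1], brk[1] + 1, dcn[brk[1]]),
               residue = brk[1])
  }
  if (validate) validate_backbone(st)
  st
}

#' Validate backbone covalent geometry
#'
#' Checks that all N-CA, CA-C and C-N(next) bonded distances lie within
#' +/- 20% of their ideal values and that coordinates are finite.
#'
#' @param state a [cg_backbone].
#' @param tol relative tolerance (default 0.2).
#' @return invisibly `TRUE`; raises a classed error otherwise.
#' @export
validate_backbone <- function(state, tol = 0.2) {
  if (any(!is.finite(state$x)))
    cg_error("cg_geometry_error", "non-finite backbone coordinates")
  n <- state$nres
  chk <- function(a, b, ideal, label) {
    d <- sqrt(rowSums((a - b)^2))
    bad <- which(abs(d - ideal) > tol * ideal)
    if (length(bad))
      cg_error("cg_geometry_error",
               sprintf("%s bond of residue %d is %.3f A (ideal %.3f)",
                       label, bad[1], d[bad[1]], ideal), residue = bad[1])
  }
  chk(state$x[atom_row(1:n, "N"), , drop = FALSE],
      state$x[atom_row(1:n, "CA"), , drop = FALSE], GEOM$b_n_ca, "N-CA")
  chk(state$x[atom_row(1:n, "CA"), , drop = FALSE],
      state$x[atom_row(1:n, "C"), , drop = FALSE], GEOM$b_ca_c, "CA-C")
  if (n > 1)
    chk(state$x[atom_row(1:(n - 1), "C"), , drop = FALSE],
        state$x[atom_row(2:n, "N"), , drop = FALSE], GEOM$b_c_n, "C-N")
  invisible(TRUE)
}

#' Backbone dihedral angles
#'
#' Returns the (phi, psi) dihedrals in radians; phi of the first residue and
#' psi of the last are `NA` (undefined without a neighboring residue).
#'
#' @param state a [cg_backbone].
#' @return a two-column matrix `phi`, `psi` with one row per residue.
#' @export
backbone_dihedrals <- function(state) {
  n <- state$nres
  x <- state$x
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1)
      phi[i] <- dihedral_angle(x[atom_row(i - 1, "C"), ], x[atom_row(i, "N"), ],
                               x[atom_row(i, "CA"), ], x[atom_row(i, "C"), ])
    if (i < n)
      psi[i] <- dihedral_angle(x[atom_row(i, "N"), ], x[atom_row(i, "CA"), ],
                               x[atom_row(i, "C"), ], x[atom_row(i + 1, "N"), ])
  }
  cbind(phi = phi, psi = psi)
}

#' Extract C-alpha coordinates
#' @param state a [cg_backbone].
#' @return `nres` by 3 matrix.
#' @export
ca_coords <- function(state) {
  state$x[atom_row(seq_len(state$nres), "CA"), , drop = FALSE]
}

#' @export
print.cg_backbone <- function(x, ...) {
  cat(sprintf("<cg_backbone: %d residues, %d atoms>\n", x$nres, 3 * x$nres))
  cat("  sequence:", paste(x$seq, collapse = ""), "\n")
  invisible(x)
}
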