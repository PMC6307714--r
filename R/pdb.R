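#' Read a backbone from a PDB file
#'
#' Reads the N, CA and C ATOM records of a (possibly multi-MODEL) PDB file.
#' All derived atoms (O, H, C-beta) are always recomputed from the backbone,
#' never read.  Multi-MODEL files are treated as trajectories.
#'
#' @param path PDB file path.
#' @param model model number to extract, or `"all"` for a list of states.
#' @param validate passed to [build_topology()].
#' @return a [cg_backbone], or a list of them when `model = "all"`.
#' @export
read_backbone_pdb <- function(path, model = 1, validate = TRUE) {
  if (!file.exists(path))
    cg_error("cg_io_error", sprintf("cannot read PDB file '%s'", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- pdb$atom$elety %in% c("N", "CA", "C") & pdb$atom$type == "ATOM"
  atom <- pdb$atom[sel, , drop = FALSE]
  if (nrow(atom) == 0)
    cg_error("cg_io_error", sprintf("no backbone atoms in '%s'", path))
  # map (chain, resno) to a dense 1-based residue index in file order
  key <- paste(atom$chain, atom$resno)
  res_idx <- match(key, unique(key))
  resnames <- atom$resid[!duplicated(key)]
  sequence <- unname(AA_ONE[resnames])
  if (anyNA(sequence))
    cg_error("cg_io_error",
             sprintf("non-canonical residue '%s' in '%s'",
                     resnames[which(is.na(sequence))[1]], path))
  nmodels <- if (!is.null(pdb$xyz) && is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  xyz_rows <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  cols <- as.vector(rbind(3 * (which(sel)) - 2, 3 * which(sel) - 1,
                          3 * which(sel)))
  one_model <- function(k) {
    v <- xyz_rows[k, cols]
    m <- matrix(v, ncol = 3, byrow = TRUE)
    coords <- data.frame(res = res_idx, atom = atom$elety,
                         x = m[, 1], y = m[, 2], z = m[, 3])
    build_topology(sequence, coords, validate = validate)
  }
  if (identical(model, "all")) return(lapply(seq_len(nmodels), one_model))
  one_model(model)
}

#' Write backbone state(s) to a PDB file
#'
#' Writes standard ATOM records for the N, CA and C atoms.  A list of states
#' is written as a multi-MODEL trajectory.  Writes are atomic (temp file then
#' rename).
#'
#' @param state a [cg_backbone] or a list of them (a trajectory).
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_backbone_pdb <- function(state, path) {
  states <- if (inherits(state, "cg_backbone")) list(state) else state
  tmp <- tempfile(tmpdir = dirname(path))
  con <- file(tmp, "w")
  closed <- FALSE
  on.exit({ if (!closed) close(con) }, add = TRUE)
  multi <- length(states) > 1
  for (k in seq_along(states)) {
    st <- states[[k]]
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    serial <- 0L
    lines <- character(3 * st$nres)
    for (i in seq_len(st$nres)) {
      for (atom in c("N", "CA", "C")) {
        serial <- serial + 1L
        xyz <- st$x[atom_row(i, atom), ]
        lines[serial] <- sprintf(
          "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", atom), AA_THREE[st$seq[i]], i,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, substr(atom, 1, 1))
      }
    }
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  close(con)
  closed <- TRUE
  file.rename(tmp, path)
  invisible(path)
}
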