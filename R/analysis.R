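# Trajectory observables: best-fit C-alpha RMSD (with terminal exclusion),
# radius of gyration, heat capacity by the fluctuation relation, hydrogen
# bond counting, greedy RMSD clustering and RMSD histograms.

as_ca_matrix <- function(x) {
  if (inherits(x, "cg_backbone")) return(ca_coords(x))
  stopifnot(is.matrix(x), ncol(x) == 3)
  x
}

# Kabsch superposition: rotation (and translation) minimizing RMSD of B onto
# A; proper rotation enforced via the determinant sign.
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, center_a = ca, center_b = cb,
       aligned_b = B0 %*% t(R) + matrix(ca, nrow(B), 3, byrow = TRUE))
}

#' Best-fit C-alpha RMSD
#'
#' Optimal-rotation (Kabsch) root-mean-square deviation over C-alpha atoms,
#' excluding `exclude_termini` residues at each end (default 3, the
#' convention used for reporting folding accuracy; pass 0 to keep all).
#'
#' @param a,b [cg_backbone] objects or `nres` x 3 C-alpha matrices with equal
#'   residue counts.
#' @param exclude_termini residues dropped at each terminus.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(a, b, exclude_termini = 3) {
  A <- as_ca_matrix(a); B <- as_ca_matrix(b)
  if (nrow(A) != nrow(B))
    cg_error("cg_shape_error",
             sprintf("residue counts differ: %d vs %d", nrow(A), nrow(B)))
  n <- nrow(A)
  stopifnot(exclude_termini >= 0, 2 * exclude_termini < n)
  keep <- (1 + exclude_termini):(n - exclude_termini)
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  fit <- kabsch(A, B)
  sqrt(mean(rowSums((A - fit$aligned_b)^2)))
}

#' Radius of gyration of the C-alpha trace
#'
#' Root-mean-square distance of the C-alpha atoms from their centroid.
#'
#' @param frame a [cg_backbone] or C-alpha matrix.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame) {
  X <- as_ca_matrix(frame)
  C <- colMeans(X)
  sqrt(mean(rowSums(sweep(X, 2, C)^2)))
}

#' Self-avoiding-walk reference radius of gyration
#'
#' The empirical reference for chemically denatured proteins,
#' `Rg = 1.9 * Nres^0.6` Angstrom.
#'
#' @param nres number of residues.
#' @return reference Rg in Angstrom.
#' @export
saw_reference <- function(nres) {
  stopifnot(all(nres >= 1))
  1.9 * nres^0.6
}

#' Heat capacity from energy fluctuations
#'
#' `Cp = var(E) / T^2` with the unbiased (n-1) sample variance; invariant
#' under adding a constant to all energies.
#'
#' @param energies numeric vector of sampled potential energies (>= 2).
#' @param temperature temperature of the ensemble (> 0).
#' @return Cp in model units.
#' @export
heat_capacity <- function(energies, temperature) {
  stopifnot(length(energies) >= 2, temperature > 0)
  stats::var(energies) / temperature^2
}

#' Count backbone hydrogen bonds in a frame
#'
#' Number of (donor, acceptor) pairs whose geometric score from
#' [eval_hbond()] is at least `threshold`.  The count is nonincreasing in the
#' threshold.
#'
#' @param state a [cg_backbone].
#' @param pset a `cg_params` (geometry constants; the magnitude is
#'   irrelevant to the score).
#' @param threshold score threshold in `[0, 1]` (default 0.5).
#' @param frame optional precomputed `cg_frame`.
#' @return integer count.
#' @export
hbond_count <- function(state, pset = NULL, threshold = 0.5, frame = NULL) {
  if (is.null(pset)) pset <- new_parameter_set()
  if (is.null(frame)) frame <- place_virtual_sites(state, jacobian = FALSE)
  hb <- eval_hbond(pset, state, frame)
  sum(hb$scores$score >= threshold)
}

#' Greedy leader clustering of trajectory frames by RMSD
#'
#' Frames are scanned in order; each joins the first existing cluster whose
#' leader is within `rmsd_cutoff`, otherwise it founds a new cluster.  The
#' centroid of a cluster is the member minimizing the mean RMSD to the other
#' members.  Clusters are returned ordered by size (ties broken by first
#' frame index), so `clusters[[1]]` is the largest.
#'
#' @param frames list of [cg_backbone] or C-alpha matrices.
#' @param rmsd_cutoff leader distance cutoff in Angstrom (default 3).
#' @param exclude_termini passed to [ca_rmsd()] (default 0: cluster on all
#'   residues).
#' @return list with `clusters` (list of frame index vectors), `centroids`
#'   (frame index per cluster) and `assignment` (cluster id per frame).
#' @export
cluster_frames <- function(frames, rmsd_cutoff = 3, exclude_termini = 0) {
  stopifnot(length(frames) >= 1)
  mats <- lapply(frames, as_ca_matrix)
  leaders <- integer(0)
  members <- list()
  assign <- integer(length(mats))
  for (f in seq_along(mats)) {
    placed <- FALSE
    for (cl in seq_along(leaders)) {
      if (ca_rmsd(mats[[leaders[cl]]], mats[[f]],
                  exclude_termini = exclude_termini) <= rmsd_cutoff) {
        members[[cl]] <- c(members[[cl]], f)
        assign[f] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, f)
      members[[length(leaders)]] <- f
      assign[f] <- length(leaders)
    }
  }
  sizes <- lengths(members)
  ord <- order(-sizes, vapply(members, `[`, 1L, 1L))
  members <- members[ord]
  assign <- match(assign, ord)
  centroids <- vapply(members, function(ix) {
    if (length(ix) == 1) return(ix)
    meanr <- vapply(ix, function(f)
      mean(vapply(setdiff(ix, f), function(g)
        ca_rmsd(mats[[f]], mats[[g]], exclude_termini = exclude_termini),
        1)), 1)
    ix[which.min(meanr)]
  }, 1L)
  list(clusters = members, centroids = centroids, assignment = assign)
}

#' RMSD-to-reference histogram with equilibration discard
#'
#' Drops the initial `discard_fraction` of the trajectory (default the first
#' third) and histograms the best-fit C-alpha RMSD of the remaining frames to
#' the reference.
#'
#' @param frames list of frames (trajectory order).
#' @param reference reference frame.
#' @param discard_fraction fraction of initial frames discarded.
#' @param breaks passed to [graphics::hist()] semantics via [base::cut()];
#'   either a bin width (scalar) or explicit break points.
#' @param exclude_termini passed to [ca_rmsd()].
#' @return list with `rmsd` (retained values), `counts`, `breaks`.
#' @export
rmsd_histogram <- function(frames, reference, discard_fraction = 1 / 3,
                           breaks = 0.5, exclude_termini = 3) {
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  n <- length(frames)
  keep <- frames[(floor(n * discard_fraction) + 1L):n]
  r <- vapply(keep, ca_rmsd, 1, b = reference,
              exclude_termini = exclude_termini)
  if (length(breaks) == 1) {
    hi <- max(r, breaks) + breaks
    breaks <- seq(0, hi, by = breaks)
  }
  counts <- as.vector(table(cut(r, breaks, include.lowest = TRUE)))
  list(rmsd = r, counts = counts, breaks = breaks)
}

#' Per-frame trajectory statistics
#'
#' @param frames list of [cg_backbone].
#' @param pset a `cg_params` (for hydrogen-bond scoring).
#' @param reference optional reference frame for RMSD.
#' @param exclude_termini passed to [ca_rmsd()].
#' @return data frame with columns `frame`, `rg`, `n_hbond` and (with a
#'   reference) `rmsd`.
#' @export
trajectory_stats <- function(frames, pset = NULL, reference = NULL,
                             exclude_termini = 3) {
  if (is.null(pset)) pset <- new_parameter_set()
  out <- data.frame(
    frame = seq_along(frames),
    rg = vapply(frames, radius_of_gyration, 1),
    n_hbond = vapply(frames, function(f) hbond_count(f, pset), 1L)
  )
  if (!is.null(reference))
    out$rmsd <- vapply(frames, ca_rmsd, 1, b = reference,
                       exclude_termini = exclude_termini)
  out
}
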