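# Discrete oriented side-chain beads: rotamer library and factor graph.

#' Bundled idealized rotamer library
#'
#' A deterministic fixture library: each residue type gets 1-3 discrete bead
#' states (glycine and alanine a single state at the C-beta; proline two
#' pucker-like states; all others three chi1-like states at gauche-/trans/
#' gauche+), each with a local position (in the residue backbone frame), a
#' local orientation unit vector along the C-beta -> bead axis, and a prior
#' weight.  The file format (see [read_rotamer_library()]) supports up to 6
#' states per residue; real PDB-derived libraries can be loaded from file.
#'
#' @return named list (one entry per residue code) with matrices `pos`
#'   (states x 3), `ori` (states x 3) and vector `w` (weights summing to 1).
#' @export
default_rotamer_library <- function() {
  # ideal backbone triad to define the local frame once
  nn <- c(GEOM$b_n_ca * sin(GEOM$a_n_ca_c / 2),
          GEOM$b_n_ca * cos(GEOM$a_n_ca_c / 2), 0)
  ca <- c(0, 0, 0)
  cc <- c(-GEOM$b_ca_c * sin(GEOM$a_n_ca_c / 2),
          GEOM$b_ca_c * cos(GEOM$a_n_ca_c / 2), 0)
  A <- matrix(c(nn, ca, cc), 1, 9)
  fr <- frame_rows(A)[1, ]
  R <- cbind(fr[1:3], fr[4:6], fr[7:9])   # columns ex, ey, ez
  to_local <- function(v) as.vector(t(R) %*% (v - ca))
  cb <- place_cb_rows(A)[1, ]
  axis <- (cb - ca) / sqrt(sum((cb - ca)^2))
  # an arbitrary unit vector perpendicular to the CA->CB axis
  perp <- c(axis[2], -axis[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  tet <- acos(-1 / 3)
  bead_at <- function(len, chi) {
    if (len == 0) return(cb)
    d <- cos(pi - tet) * axis + sin(pi - tet) *
      (cos(chi) * perp + sin(chi) * as.vector(row_cross(rbind(axis),
                                                        rbind(perp))))
    cb + len * d
  }
  # crude bead distances from the C-beta by side-chain size (Angstrom)
  len <- c(A = 0, G = 0, S = 1.0, C = 1.2, T = 1.1, V = 1.1, P = 0.9,
           N = 1.6, D = 1.6, I = 1.8, L = 1.8, Q = 2.2, E = 2.2, M = 2.2,
           H = 2.2, F = 2.4, K = 2.8, R = 3.1, W = 2.7, Y = 2.9)
  lib <- list()
  for (a in AA_CODES) {
    if (a %in% c("A", "G")) {
      pos <- rbind(to_local(cb))
      ori <- rbind(to_local(cb + axis) - to_local(cb))
      w <- 1
    } else if (a == "P") {
      chis <- c(-30, 30) * pi / 180
      pos <- t(vapply(chis, function(ch) to_local(bead_at(len[a], ch)),
                      numeric(3)))
      w <- c(0.55, 0.45)
      ori <- pos # placeholder, fixed below
    } else {
      chis <- c(-60, 180, 60) * pi / 180
      pos <- t(vapply(chis, function(ch) to_local(bead_at(len[a], ch)),
                      numeric(3)))
      w <- c(0.45, 0.35, 0.20)
      ori <- pos
    }
    cb_loc <- to_local(cb)
    ori <- pos - matrix(cb_loc, nrow(pos), 3, byrow = TRUE)
    nrm <- sqrt(rowSums(ori^2))
    zerolen <- which(nrm < 1e-9)
    if (length(zerolen))
      ori[zerolen, ] <- matrix(to_local(cb + axis) - cb_loc,
                               length(zerolen), 3, byrow = TRUE)
    ori <- ori / sqrt(rowSums(ori^2))
    lib[[a]] <- list(pos = pos, ori = ori, w = w / sum(w))
  }
  lib
}

# Orientation unit vectors of the 5 backbone interaction sites, plus the
# pair of points defining each (for gradient propagation).
bb_site_info <- function(state, frame, i) {
  x <- state$x
  list(
    H  = if (frame$has_H[i])
      list(pos = frame$H[i, ], from = list(kind = "N", i = i),
           to = list(kind = "H", i = i)) else NULL,
    O  = list(pos = frame$O[i, ], from = list(kind = "C", i = i),
              to = list(kind = "O", i = i)),
    N  = list(pos = x[atom_row(i, "N"), ], from = list(kind = "CA", i = i),
              to = list(kind = "N", i = i)),
    CA = list(pos = x[atom_row(i, "CA"), ], from = list(kind = "CA", i = i),
              to = list(kind = "CB", i = i)),
    C  = list(pos = x[atom_row(i, "C"), ], from = list(kind = "C", i = i),
              to = list(kind = "O", i = i))
  )
}

site_point <- function(state, frame, kind, i) {
  switch(kind,
         N = state$x[atom_row(i, "N"), ],
         CA = state$x[atom_row(i, "CA"), ],
         C = state$x[atom_row(i, "C"), ],
         O = frame$O[i, ],
         H = frame$H[i, ],
         CB = frame$CB[i, ])
}

#' Build the side-chain rotamer factor graph
#'
#' Places every library state of every residue in its backbone frame,
#' computes node energies (prior `-T log w` plus bead-backbone pair energies
#' against the five backbone sites of residues at sequence separation >= 2)
#' and edge energy tables (bead-bead pair energies) for all residue pairs
#' within interaction range.
#'
#' @param state a [cg_backbone].
#' @param frame a `cg_frame` with Jacobians.
#' @param pset a `cg_params`.
#' @param rotlib rotamer library (see [default_rotamer_library()]).
#' @param temperature temperature entering the prior term.
#' @param want_grad also store per-state geometry gradients (needed by
#'   [sidechain_forces()]).
#' @param want_param also store parameter-derivative bases.
#' @return an object of class `cg_rotamer_graph`.
#' @export
build_rotamer_graph <- function(state, frame, pset, rotlib,
                                temperature = 1, want_grad = TRUE,
                                want_param = FALSE) {
  n <- state$nres
  x <- state$x
  rN <- atom_row(1:n, "N"); rCA <- atom_row(1:n, "CA"); rC <- atom_row(1:n, "C")
  own <- cbind(x[rN, , drop = FALSE], x[rCA, , drop = FALSE],
               x[rC, , drop = FALSE])
  nstates <- vapply(state$seq, function(a) length(rotlib[[a]]$w), 1L)
  sidx <- cbind(res = rep(seq_len(n), nstates),
                state = unlist(lapply(nstates, seq_len)))
  m <- nrow(sidx)
  locpos <- t(vapply(seq_len(m), function(r)
    rotlib[[state$seq[sidx[r, 1]]]]$pos[sidx[r, 2], ], numeric(3)))
  locori <- t(vapply(seq_len(m), function(r)
    rotlib[[state$seq[sidx[r, 1]]]]$ori[sidx[r, 2], ], numeric(3)))
  Abig <- own[sidx[, 1], , drop = FALSE]
  f_pos <- function(A) place_local_rows(A, locpos, origin = TRUE)
  f_ori <- function(A) place_local_rows(A, locori, origin = FALSE)
  bead_pos <- f_pos(Abig)
  bead_ori <- f_ori(Abig)
  Jpos <- Jori <- NULL
  if (want_grad) {
    Jpos <- jac_complex(f_pos, Abig)
    Jori <- jac_complex(f_ori, Abig)
  }
  # state row lookup: rows of state r for residue i
  rows_of <- split(seq_len(m), sidx[, 1])

  priors <- lapply(seq_len(n), function(i)
    -temperature * log(rotlib[[state$seq[i]]]$w))
  node_e <- priors

  # ---- bead-backbone node terms -------------------------------------------
  bb_rows <- NULL
  if (n >= 3) {
    ridx <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      for (site in BB_SITES) {
        if (site == "H" && !frame$has_H[j]) next
        for (r in rows_of[[i]])
          ridx[[length(ridx) + 1L]] <- c(r, j, match(site, BB_SITES))
      }
    }
    if (length(ridx)) {
      tab <- do.call(rbind, ridx)
      # prune by distance to keep only rows within the cutoff
      sp <- t(vapply(seq_len(nrow(tab)), function(q)
        site_point(state, frame, BB_SITES[tab[q, 3]], tab[q, 2]), numeric(3)))
      keep <- sqrt(rowSums((bead_pos[tab[, 1], , drop = FALSE] - sp)^2)) <
        pset$config$bb_cutoff
      tab <- tab[keep, , drop = FALSE]
      sp <- sp[keep, , drop = FALSE]
      if (nrow(tab)) {
        # site orientations
        so <- matrix(0, nrow(tab), 3)
        from_pt <- matrix(0, nrow(tab), 3)
        to_pt <- matrix(0, nrow(tab), 3)
        for (q in seq_len(nrow(tab))) {
          j <- tab[q, 2]; site <- BB_SITES[tab[q, 3]]
          ends <- switch(site,
                         H = c("N", "H"), O = c("C", "O"), N = c("CA", "N"),
                         CA = c("CA", "CB"), C = c("C", "O"))
          from_pt[q, ] <- site_point(state, frame, ends[1], j)
          to_pt[q, ] <- site_point(state, frame, ends[2], j)
        }
        dv <- to_pt - from_pt
        so <- dv / sqrt(rowSums(dv^2))
        pk <- vapply(seq_len(nrow(tab)), function(q)
          bb_pair_index(BB_SITES[tab[q, 3]],
                        state$seq[sidx[tab[q, 1], 1]]), 1L)
        bb_rows <- list(tab = tab, site_pos = sp, site_ori = so,
                        from_pt = from_pt, to_pt = to_pt, pair_k = pk)
        ev <- group_pair_eval(pset$bb_pairs, pk,
                              bead_pos[tab[, 1], , drop = FALSE],
                              bead_ori[tab[, 1], , drop = FALSE],
                              sp, so, want_param)
        bb_rows$ev <- ev
        for (q in seq_len(nrow(tab))) {
          r <- tab[q, 1]
          i <- sidx[r, 1]; s <- sidx[r, 2]
          node_e[[i]][s] <- node_e[[i]][s] + ev$energy[q]
        }
      }
    }
  }

  # ---- bead-bead edges ----------------------------------------------------
  edges <- NULL
  edge_e <- list()
  edge_rows <- list()
  cut <- pset$config$sc_cutoff
  epairs <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ri <- rows_of[[i]]; rj <- rows_of[[j]]
      dmin <- min(vapply(ri, function(a) min(sqrt(colSums(
        (t(bead_pos[rj, , drop = FALSE]) - bead_pos[a, ])^2))), 1))
      if (dmin < cut) epairs[[length(epairs) + 1L]] <- c(i, j)
    }
  }
  if (length(epairs)) {
    edges <- do.call(rbind, epairs)
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      ri <- rows_of[[i]]; rj <- rows_of[[j]]
      grid <- expand.grid(a = ri, b = rj)
      ev <- sc_pair_batch(pset, state$seq[i], state$seq[j],
                          bead_pos[grid$a, , drop = FALSE],
                          bead_ori[grid$a, , drop = FALSE],
                          bead_pos[grid$b, , drop = FALSE],
                          bead_ori[grid$b, , drop = FALSE],
                          want_param)
      edge_e[[e]] <- matrix(ev$energy, length(ri), length(rj))
      edge_rows[[e]] <- list(grid = grid, ev = ev)
    }
  }

  structure(list(
    n = n, nstates = nstates, node_e = node_e, edges = edges,
    edge_e = edge_e, seq = state$seq,
    sidx = sidx, rows_of = rows_of,
    bead_pos = bead_pos, bead_ori = bead_ori, Jpos = Jpos, Jori = Jori,
    bb_rows = bb_rows, edge_rows = edge_rows,
    temperature = temperature, want_param = want_param
  ), class = "cg_rotamer_graph")
}

# Evaluate pair rows grouped by parameter block index; returns row-aligned
# energies/gradients (and parameter bases when requested).
group_pair_eval <- function(blocks, pair_k, Y1, N1, Y2, N2, want_param) {
  m <- length(pair_k)
  out <- list(energy = numeric(m),
              gY1 = matrix(0, m, 3), gN1 = matrix(0, m, 3),
              gY2 = matrix(0, m, 3), gN2 = matrix(0, m, 3))
  if (want_param) {
    out$dkappa <- numeric(m)
    out$b_radial <- matrix(0, m, blocks[[1]]$radial$n)
    out$b_angular <- matrix(0, m, blocks[[1]]$angular$n)
    out$b_ang1 <- matrix(0, m, blocks[[1]]$ang1$n)
    out$b_ang2 <- matrix(0, m, blocks[[1]]$ang2$n)
  }
  for (k in unique(pair_k)) {
    sel <- which(pair_k == k)
    ev <- pair_eval_batch(blocks[[k]], Y1[sel, , drop = FALSE],
                          N1[sel, , drop = FALSE], Y2[sel, , drop = FALSE],
                          N2[sel, , drop = FALSE], want_param)
    out$energy[sel] <- ev$energy
    out$gY1[sel, ] <- ev$gY1; out$gN1[sel, ] <- ev$gN1
    out$gY2[sel, ] <- ev$gY2; out$gN2[sel, ] <- ev$gN2
    if (want_param) {
      out$dkappa[sel] <- ev$dkappa
      out$b_radial[sel, ] <- ev$b_radial
      out$b_angular[sel, ] <- ev$b_angular
      out$b_ang1[sel, ] <- ev$b_ang1
      out$b_ang2[sel, ] <- ev$b_ang2
    }
  }
  out
}

#' @export
print.cg_rotamer_graph <- function(x, ...) {
  cat(sprintf("<cg_rotamer_graph: %d nodes (states %s), %d edges>\n",
              x$n, paste(range(x$nstates), collapse = "-"),
              if (is.null(x$edges)) 0L else nrow(x$edges)))
  invisible(x)
}
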