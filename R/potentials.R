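# Parameterized energy terms and their analytic derivatives with respect to
# both coordinates and trainable parameters.

# ---------------------------------------------------------------------------
# Oriented pair potential
#   V = kappa * ( V_radial(r12) + ang1(-n1.n12) * ang2(n2.n12) * V_angular(r12) )
# with r12 = |y1 - y2| and n12 = (y1 - y2)/r12.
# ---------------------------------------------------------------------------

# Vectorized evaluation over m pair rows.  Returns energy, gradients with
# respect to y1, n1, y2, n2 (each m x 3) and, when `want_param`, the exact
# parameter derivatives (kappa plus spline bases).
pair_eval_batch <- function(pp, Y1, N1, Y2, N2, want_param = FALSE) {
  D <- unname(Y1 - Y2)
  r <- sqrt(rowSums(D^2))
  if (any(r == 0))
    cg_error("cg_degenerate_geometry_error", "coincident pair positions")
  nh <- D / r
  c1 <- -(rowSums(unname(N1) * nh))
  c2 <- rowSums(unname(N2) * nh)
  R  <- spline_eval(pp$radial, r, basis = want_param)
  Va <- spline_eval(pp$angular, r, basis = want_param)
  A1 <- spline_eval(pp$ang1, c1, basis = want_param)
  A2 <- spline_eval(pp$ang2, c2, basis = want_param)
  k <- pp$kappa
  bracket <- R$value + A1$value * A2$value * Va$value
  E <- k * bracket
  dVdr  <- k * (R$deriv + A1$value * A2$value * Va$deriv)
  dVdc1 <- k * A1$deriv * A2$value * Va$value
  dVdc2 <- k * A1$value * A2$deriv * Va$value
  # chain rule: dr/dy1 = nh; dc/dy1 through dn12/dy1 = (I - nh nh^T)/r
  g_c1_y1 <- -(N1 - c_times(-c1, nh)) / r     # d(-n1.nh)/dy1
  g_c2_y1 <- (N2 - c_times(c2, nh)) / r       # d(n2.nh)/dy1
  gY1 <- dVdr * nh + dVdc1 * g_c1_y1 + dVdc2 * g_c2_y1
  out <- list(
    energy = E,
    gY1 = gY1, gY2 = -gY1,
    gN1 = -dVdc1 * nh,
    gN2 = dVdc2 * nh
  )
  if (want_param) {
    out$dkappa <- bracket
    out$b_radial <- k * R$basis
    out$b_angular <- (k * A1$value * A2$value) * Va$basis
    out$b_ang1 <- (k * A2$value * Va$value) * A1$basis
    out$b_ang2 <- (k * A1$value * Va$value) * A2$basis
  }
  out
}

c_times <- function(s, M) M * s  # row-scalar times m x 3 matrix

#' Evaluate the oriented pair potential for a single pair
#'
#' The pair energy is `kappa * (V_radial(r) + ang1(-n1.n12) ang2(n2.n12)
#' V_angular(r))`, with all four curves cubic splines.  Radial curves vanish
#' (value and derivative) at and beyond the cutoff.
#'
#' @param pp a pair-parameter block (element of `pset$sc_pairs` or
#'   `pset$bb_pairs`).
#' @param y1,y2 3-vectors, positions (Angstrom).
#' @param n1,n2 unit 3-vectors, orientations.
#' @param want_param also return exact parameter derivatives.
#' @return list with `energy`, coordinate gradients `gY1`, `gN1`, `gY2`,
#'   `gN2`, and (optionally) `dkappa` and the spline basis blocks.
#' @export
eval_pair <- function(pp, y1, n1, y2, n2, want_param = FALSE) {
  res <- pair_eval_batch(pp, rbind(y1), rbind(n1), rbind(y2), rbind(n2),
                         want_param = want_param)
  res$energy <- unname(res$energy[1])
  res$gY1 <- as.vector(res$gY1); res$gN1 <- as.vector(res$gN1)
  res$gY2 <- as.vector(res$gY2); res$gN2 <- as.vector(res$gN2)
  res
}

# Symmetrized side-chain pair evaluation in the caller's (1, 2) order.
# Arguments are given with bead 1 of type `a`, bead 2 of type `b`; the
# canonical parameter block of the unordered pair is used, with bead of the
# canonical-first type in slot 1.  For like-type pairs the two orderings are
# averaged so the interaction is exchange-symmetric.
sc_pair_batch <- function(pset, a, b, Y1, N1, Y2, N2, want_param = FALSE) {
  ix <- sc_pair_index(a, b)
  pp <- pset$sc_pairs[[ix$index]]
  if (a == b) {
    r1 <- pair_eval_batch(pp, Y1, N1, Y2, N2, want_param)
    r2 <- pair_eval_batch(pp, Y2, N2, Y1, N1, want_param)
    out <- list(energy = (r1$energy + r2$energy) / 2,
                gY1 = (r1$gY1 + r2$gY2) / 2, gN1 = (r1$gN1 + r2$gN2) / 2,
                gY2 = (r1$gY2 + r2$gY1) / 2, gN2 = (r1$gN2 + r2$gN1) / 2)
    if (want_param) {
      for (f in c("dkappa", "b_radial", "b_angular", "b_ang1", "b_ang2"))
        out[[f]] <- (r1[[f]] + r2[[f]]) / 2
    }
    out$pair_index <- ix$index
    return(out)
  }
  if (!ix$swapped) {
    out <- pair_eval_batch(pp, Y1, N1, Y2, N2, want_param)
  } else {
    r <- pair_eval_batch(pp, Y2, N2, Y1, N1, want_param)
    out <- list(energy = r$energy, gY1 = r$gY2, gN1 = r$gN2,
                gY2 = r$gY1, gN2 = r$gN1)
    if (want_param)
      for (f in c("dkappa", "b_radial", "b_angular", "b_ang1", "b_ang2"))
        out[[f]] <- r[[f]]
  }
  out$pair_index <- ix$index
  out
}

# ---------------------------------------------------------------------------
# Environment (burial) potential: V_env = sum_i v_env^{a_i}(N_i)
# ---------------------------------------------------------------------------

#' Evaluate the environment potential
#'
#' Sums the per-residue-type burial curves at the smooth neighbor counts.
#' Counts outside the curve domain are clamped with zero slope.
#'
#' @param pset a `cg_params`.
#' @param burial per-residue smooth counts from [burial_counts()].
#' @param sequence residue codes.
#' @param want_param also return the coefficient basis rows.
#' @return list with `energy`, `dN` (derivative with respect to each count)
#'   and optionally `basis` (residues x coefficients of the owning curve) for
#'   the parameter gradient.
#' @export
eval_env <- function(pset, burial, sequence, want_param = FALSE) {
  n <- length(sequence)
  val <- dN <- numeric(n)
  basis <- if (want_param) matrix(0, n, pset$config$env_n) else NULL
  for (a in unique(sequence)) {
    sel <- which(sequence == a)
    ev <- spline_eval(pset$env[[a]], burial[sel], basis = want_param)
    val[sel] <- ev$value
    dN[sel] <- ev$deriv
    if (want_param) basis[sel, ] <- ev$basis
  }
  list(energy = sum(val), per_residue = val, dN = dN, basis = basis)
}

# ---------------------------------------------------------------------------
# Ramachandran term with beta-sheet bias
# ---------------------------------------------------------------------------

#' Bundled Ramachandran table
#'
#' Builds a smooth periodic (phi, psi) energy grid per residue-context class
#' from a mixture of von Mises basins (alpha, beta, left-handed alpha).  The
#' bundled table keeps three context classes (general, pre-proline,
#' glycine); the file format supports arbitrary context keys.
#'
#' @param n grid points per dimension (period 2*pi).
#' @return a rama table list: `contexts` (named list of n x n energy grids),
#'   `n`, and the beta-region bump constants used by the sheet bias.
#' @export
make_rama_table <- function(n = 24L) {
  ang <- seq(-pi, pi, length.out = n + 1L)[1:n]
  basin <- function(phi0, psi0, kphi, kpsi, w) {
    outer(ang, ang, function(p, q)
      w * exp(kphi * (cos(p - phi0) - 1) + kpsi * (cos(q - psi0) - 1)))
  }
  d2r <- pi / 180
  mk <- function(wa, wb, wl) {
    dens <- basin(-63 * d2r, -43 * d2r, 8, 6, wa) +
      basin(-120 * d2r, 130 * d2r, 4, 3, wb) +
      basin(60 * d2r, 45 * d2r, 8, 8, wl) + 0.002
    -log(dens / max(dens))
  }
  list(contexts = list(general = mk(1.0, 0.7, 0.05),
                       prepro = mk(0.4, 1.0, 0.02),
                       gly = mk(0.4, 0.5, 0.4)),
       n = n,
       beta_bump = list(phi0 = -120 * d2r, psi0 = 130 * d2r,
                        conc = 1 / (40 * d2r)^2))
}

# context class of residue i given the sequence
rama_context <- function(sequence, i) {
  n <- length(sequence)
  if (sequence[i] == "G") return("gly")
  if (i < n && sequence[i + 1] == "P") return("prepro")
  "general"
}

# Periodic Catmull-Rom (C1) interpolation on a square grid; vectorized.
# Returns value and partial derivatives with respect to phi and psi.
rama_interp <- function(grid, phi, psi) {
  n <- nrow(grid)
  h <- 2 * pi / n
  cr_w <- function(t) cbind(((-t + 2 * t^2 - t^3) / 2),
                            ((2 - 5 * t^2 + 3 * t^3) / 2),
                            ((t + 4 * t^2 - 3 * t^3) / 2),
                            ((-t^2 + t^3) / 2))
  cr_dw <- function(t) cbind(((-1 + 4 * t - 3 * t^2) / 2),
                             ((-10 * t + 9 * t^2) / 2),
                             ((1 + 8 * t - 9 * t^2) / 2),
                             ((-2 * t + 3 * t^2) / 2))
  loc <- function(x) {
    u <- (x + pi) / h
    i <- floor(u)
    list(t = u - i, i = as.integer(i %% n))
  }
  lp <- loc(phi); lq <- loc(psi)
  wp <- cr_w(lp$t); dwp <- cr_dw(lp$t) / h
  wq <- cr_w(lq$t); dwq <- cr_dw(lq$t) / h
  m <- length(phi)
  val <- dphi <- dpsi <- numeric(m)
  for (a in 1:4) {
    ia <- (lp$i + a - 2L) %% n + 1L
    rowv <- rowd <- numeric(m)
    for (b in 1:4) {
      ib <- (lq$i + b - 2L) %% n + 1L
      g <- grid[cbind(ia, ib)]
      rowv <- rowv + wq[, b] * g
      rowd <- rowd + dwq[, b] * g
    }
    val <- val + wp[, a] * rowv
    dphi <- dphi + dwp[, a] * rowv
    dpsi <- dpsi + wp[, a] * rowd
  }
  list(value = val, dphi = dphi, dpsi = dpsi)
}

# smooth periodic bump marking the beta region (for the sheet bias)
beta_bump <- function(rama, phi, psi) {
  b <- rama$beta_bump
  v <- exp(b$conc * (cos(phi - b$phi0) - 1) + b$conc * (cos(psi - b$psi0) - 1))
  list(value = v,
       dphi = -b$conc * sin(phi - b$phi0) * v,
       dpsi = -b$conc * sin(psi - b$psi0) * v)
}

#' Evaluate the Ramachandran energy at given angles
#'
#' Periodic C1 interpolation of the context grid plus the trainable
#' beta-sheet bias times a smooth bump over the beta region.
#'
#' @param pset a `cg_params`.
#' @param phi,psi angles in radians (any real value; wrapped).
#' @param context context class name (a key of `pset$rama$contexts`).
#' @return list with `value`, `dphi`, `dpsi` and `dbias` (derivative with
#'   respect to the sheet-bias parameter).
#' @export
eval_rama <- function(pset, phi, psi, context = "general") {
  grid <- pset$rama$contexts[[context]]
  if (is.null(grid)) grid <- pset$rama$contexts[["general"]]
  base <- rama_interp(grid, phi, psi)
  bump <- beta_bump(pset$rama, phi, psi)
  list(value = base$value + pset$sheet_bias * bump$value,
       dphi = base$dphi + pset$sheet_bias * bump$dphi,
       dpsi = base$dpsi + pset$sheet_bias * bump$dpsi,
       dbias = bump$value)
}

# Full backbone Ramachandran energy with atom gradients.
rama_term <- function(state, pset) {
  n <- state$nres
  x <- state$x
  grad <- matrix(0, 3 * n, 3)
  energy <- 0
  dbias <- 0
  if (n < 3) return(list(energy = 0, grad = grad, dbias = 0))
  for (i in 2:(n - 1)) {
    ap <- list(x[atom_row(i - 1, "C"), ], x[atom_row(i, "N"), ],
               x[atom_row(i, "CA"), ], x[atom_row(i, "C"), ])
    as_ <- list(x[atom_row(i, "N"), ], x[atom_row(i, "CA"), ],
                x[atom_row(i, "C"), ], x[atom_row(i + 1, "N"), ])
    dp <- dihedral_grad(ap[[1]], ap[[2]], ap[[3]], ap[[4]])
    ds <- dihedral_grad(as_[[1]], as_[[2]], as_[[3]], as_[[4]])
    ev <- eval_rama(pset, dp$angle, ds$angle, rama_context(state$seq, i))
    energy <- energy + ev$value
    dbias <- dbias + ev$dbias
    rows_p <- c(atom_row(i - 1, "C"), atom_row(i, "N"),
                atom_row(i, "CA"), atom_row(i, "C"))
    rows_s <- c(atom_row(i, "N"), atom_row(i, "CA"),
                atom_row(i, "C"), atom_row(i + 1, "N"))
    grad[rows_p, ] <- grad[rows_p, ] + ev$dphi * dp$g
    grad[rows_s, ] <- grad[rows_s, ] + ev$dpsi * ds$g
  }
  list(energy = energy, grad = grad, dbias = dbias)
}

# ---------------------------------------------------------------------------
# Hydrogen bonding
# ---------------------------------------------------------------------------

#' Backbone hydrogen-bond energy and scores
#'
#' Pairwise over donors (amide H, residues 2..n) and acceptors (carbonyl O)
#' with sequence separation at least 2.  Each pair contributes
#' `-magnitude * s_dist(r_OH) * s_ang(donor cosine) * s_ang(acceptor cosine)`
#' with compactly supported switches, so contributions beyond the distance
#' cutoff are exactly zero.  The product of switches is the pair's score in
#' `[0, 1]`.
#'
#' @param pset a `cg_params` (uses `hbond$magnitude` and fixed geometry).
#' @param state a [cg_backbone].
#' @param frame a `cg_frame`.
#' @return list with `energy`, `scores` (data frame: donor, acceptor, score),
#'   `dmagnitude`, site gradients `gH`, `gO` and direct backbone gradient
#'   `grad` (contributions through the N-H and C=O orientation vectors).
#' @export
eval_hbond <- function(pset, state, frame) {
  g <- pset$hbond$geom
  mag <- pset$hbond$magnitude
  n <- state$nres
  grad <- matrix(0, 3 * n, 3)
  gH <- matrix(0, n, 3)
  gO <- matrix(0, n, 3)
  don <- which(frame$has_H)
  sc_d <- integer(0); sc_a <- integer(0); sc_s <- numeric(0)
  energy <- 0; dmag <- 0
  r_cut <- g$dist_center + g$dist_width
  for (i in don) {
    for (j in seq_len(n)) {
      if (abs(i - j) < g$min_seq_sep) next
      hh <- frame$H[i, ]; oo <- frame$O[j, ]
      d <- oo - hh
      r <- sqrt(sum(d^2))
      if (r >= r_cut) next
      nn <- state$x[atom_row(i, "N"), ]
      cc <- state$x[atom_row(j, "C"), ]
      u_nh <- (hh - nn); lnh <- sqrt(sum(u_nh^2)); u_nh <- u_nh / lnh
      u_ho <- d / r
      u_co <- (oo - cc); lco <- sqrt(sum(u_co^2)); u_co <- u_co / lco
      u_oh <- -u_ho
      cd <- sum(u_nh * u_ho)
      ca <- sum(u_co * u_oh)
      sd <- switch_down(r, g$dist_center, g$dist_width, deriv = TRUE)
      s1 <- switch_up(cd, g$don_center, g$don_width, deriv = TRUE)
      s2 <- switch_up(ca, g$acc_center, g$acc_width, deriv = TRUE)
      score <- sd$value * s1$value * s2$value
      if (score > 0) {
        sc_d <- c(sc_d, i); sc_a <- c(sc_a, j); sc_s <- c(sc_s, score)
      }
      energy <- energy - mag * score
      dmag <- dmag - score
      if (mag != 0 && score >= 0) {
        pre <- -mag
        # distance part: d r/d O = u_ho, d r/d H = -u_ho
        gr <- pre * sd$deriv * s1$value * s2$value
        gO[j, ] <- gO[j, ] + gr * u_ho
        gH[i, ] <- gH[i, ] - gr * u_ho
        # donor cosine: depends on u_nh(N, H) and u_ho(H, O)
        gc <- pre * sd$value * s1$deriv * s2$value
        ch1 <- unit_vec_chain(nn, hh, gc * u_ho)      # through u_nh
        grad[atom_row(i, "N"), ] <- grad[atom_row(i, "N"), ] + ch1$ga
        gH[i, ] <- gH[i, ] + ch1$gb
        ch2 <- unit_vec_chain(hh, oo, gc * u_nh)      # through u_ho
        gH[i, ] <- gH[i, ] + ch2$ga
        gO[j, ] <- gO[j, ] + ch2$gb
        # acceptor cosine: depends on u_co(C, O) and u_oh(O, H)
        ga2 <- pre * sd$value * s1$value * s2$deriv
        ch3 <- unit_vec_chain(cc, oo, ga2 * u_oh)     # through u_co
        grad[atom_row(j, "C"), ] <- grad[atom_row(j, "C"), ] + ch3$ga
        gO[j, ] <- gO[j, ] + ch3$gb
        ch4 <- unit_vec_chain(oo, hh, ga2 * u_co)     # through u_oh
        gO[j, ] <- gO[j, ] + ch4$ga
        gH[i, ] <- gH[i, ] + ch4$gb
      }
    }
  }
  list(energy = energy,
       scores = data.frame(donor = sc_d, acceptor = sc_a, score = sc_s),
       dmagnitude = dmag, gH = gH, gO = gO, grad = grad)
}

# ---------------------------------------------------------------------------
# Backbone sterics (fixed)
# ---------------------------------------------------------------------------

#' Backbone steric repulsion
#'
#' Quadratic repulsion `eps * (1 - r/r_cut)^2` among the backbone N, CA,
#' C-beta and C atoms of residues at sequence separation >= 2; exactly zero
#' at and beyond `r_cut` (default 3.2 A, i.e., contact at approximately 3 A),
#' strictly decreasing inside.
#'
#' @param state a [cg_backbone].
#' @param frame a `cg_frame` (for the C-beta positions).
#' @param steric constants list (`eps`, `r_cut`, `min_seq_sep`).
#' @return list with `energy`, backbone gradient `grad` and C-beta site
#'   gradient `gCB`.
#' @export
eval_steric <- function(state, frame, steric = STERIC_DEFAULTS) {
  n <- state$nres
  kinds <- c("N", "CA", "CB", "C")
  pos <- function(i, kind) {
    if (kind == "CB") frame$CB[i, ] else state$x[atom_row(i, kind), ]
  }
  grad <- matrix(0, 3 * n, 3)
  gCB <- matrix(0, n, 3)
  energy <- 0
  rc <- steric$r_cut
  if (n >= steric$min_seq_sep + 1) {
    for (i in 1:(n - steric$min_seq_sep)) {
      for (j in (i + steric$min_seq_sep):n) {
        for (ki in kinds) for (kj in kinds) {
          d <- pos(i, ki) - pos(j, kj)
          r2 <- sum(d^2)
          if (r2 >= rc * rc) next
          r <- sqrt(r2)
          energy <- energy + steric$eps * (1 - r / rc)^2
          dEdr <- -2 * steric$eps * (1 - r / rc) / rc
          gv <- dEdr * d / r
          if (ki == "CB") gCB[i, ] <- gCB[i, ] + gv
          else grad[atom_row(i, ki), ] <- grad[atom_row(i, ki), ] + gv
          if (kj == "CB") gCB[j, ] <- gCB[j, ] - gv
          else grad[atom_row(j, kj), ] <- grad[atom_row(j, kj), ] - gv
        }
      }
    }
  }
  list(energy = energy, grad = grad, gCB = gCB)
}

# ---------------------------------------------------------------------------
# Bonded terms (fixed): stiff harmonic bonds and angles plus a harmonic
# omega dihedral keep the 3-atom backbone covalently connected.
# ---------------------------------------------------------------------------
eval_bonded <- function(state, bonded = list(k_bond = 100, k_angle = 40,
                                             k_omega = 10)) {
  n <- state$nres
  x <- state$x
  grad <- matrix(0, 3 * n, 3)
  energy <- 0
  add_bond <- function(r1, r2, ideal) {
    d <- x[r1, ] - x[r2, ]
    r <- sqrt(sum(d^2))
    energy <<- energy + 0.5 * bonded$k_bond * (r - ideal)^2
    gv <- bonded$k_bond * (r - ideal) * d / r
    grad[r1, ] <<- grad[r1, ] + gv
    grad[r2, ] <<- grad[r2, ] - gv
  }
  add_angle <- function(rows, ideal) {
    ag <- angle_grad(x[rows[1], ], x[rows[2], ], x[rows[3], ])
    energy <<- energy + 0.5 * bonded$k_angle * (ag$angle - ideal)^2
    grad[rows, ] <<- grad[rows, ] + bonded$k_angle * (ag$angle - ideal) * ag$g
  }
  for (i in seq_len(n)) {
    add_bond(atom_row(i, "N"), atom_row(i, "CA"), GEOM$b_n_ca)
    add_bond(atom_row(i, "CA"), atom_row(i, "C"), GEOM$b_ca_c)
    add_angle(c(atom_row(i, "N"), atom_row(i, "CA"), atom_row(i, "C")),
              GEOM$a_n_ca_c)
    if (i < n) {
      add_bond(atom_row(i, "C"), atom_row(i + 1, "N"), GEOM$b_c_n)
      add_angle(c(atom_row(i, "CA"), atom_row(i, "C"), atom_row(i + 1, "N")),
                GEOM$a_ca_c_n)
      add_angle(c(atom_row(i, "C"), atom_row(i + 1, "N"),
                  atom_row(i + 1, "CA")), GEOM$a_c_n_ca)
      rows <- c(atom_row(i, "CA"), atom_row(i, "C"),
                atom_row(i + 1, "N"), atom_row(i + 1, "CA"))
      dg <- dihedral_grad(x[rows[1], ], x[rows[2], ], x[rows[3], ],
                          x[rows[4], ])
      dw <- wrap_angle(dg$angle - GEOM$omega)
      energy <- energy + 0.5 * bonded$k_omega * dw^2
      grad[rows, ] <- grad[rows, ] + bonded$k_omega * dw * dg$g
    }
  }
  list(energy = energy, grad = grad)
}
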