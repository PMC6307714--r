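# Deterministic virtual-site placement (O, H, C-beta), smooth burial counts,
# and the chain-rule pullback of derived-site gradients onto backbone atoms.
#
# Placement maps are written with complex-safe primitives only (+, -, *, /,
# sqrt), so their Jacobians are obtained by complex-step differentiation,
# which is exact to machine precision: J = Im f(x + ih e_k) / h with h tiny.

CSTEP <- 1e-20

# Jacobian of a row-wise map f: (n x k) -> (n x 3) by complex step.
jac_complex <- function(f, X) {
  n <- nrow(X); k <- ncol(X)
  J <- array(0, c(n, 3, k))
  Xc <- matrix(complex(real = X, imaginary = 0), n, k)
  for (j in seq_len(k)) {
    Xp <- Xc
    Xp[, j] <- Xp[, j] + complex(imaginary = CSTEP)
    Y <- f(Xp)
    J[, , j] <- Im(Y) / CSTEP
  }
  J
}

# --- row-wise placement maps (inputs are n x 9 matrices of parent coords) ---

# carbonyl O from (CA_i, C_i, N_{i+1}): bisects the exterior CA-C-N angle in
# the peptide plane, 1.231 A from C.
place_o_rows <- function(A) {
  ca <- A[, 1:3, drop = FALSE]; cc <- A[, 4:6, drop = FALSE]
  nn <- A[, 7:9, drop = FALSE]
  u1 <- row_normalize(ca - cc)
  u2 <- row_normalize(nn - cc)
  d <- -row_normalize(u1 + u2)
  cc + GEOM$b_c_o * d
}

# last residue: extrapolate an ideal trans peptide frame from (N, CA, C)
# to obtain a pseudo next-N, then place O as usual.
place_o_last_rows <- function(A) {
  nn <- A[, 1:3, drop = FALSE]; ca <- A[, 4:6, drop = FALSE]
  cc <- A[, 7:9, drop = FALSE]
  bc <- row_normalize(cc - ca)
  nrm <- row_normalize(row_cross(ca - nn, bc))
  m2 <- row_cross(nrm, bc)
  ang <- GEOM$a_ca_c_n
  d2 <- c(-GEOM$b_c_n * cos(ang), GEOM$b_c_n * sin(ang) * cos(pi))
  nnext <- cc + d2[1] * bc + d2[2] * m2
  place_o_rows(cbind(ca, cc, nnext))
}

# amide H from (C_{i-1}, N_i, CA_i): anti-bisector in the peptide plane,
# 1.010 A from N.
place_h_rows <- function(A) {
  cp <- A[, 1:3, drop = FALSE]; nn <- A[, 4:6, drop = FALSE]
  ca <- A[, 7:9, drop = FALSE]
  u1 <- row_normalize(cp - nn)
  u2 <- row_normalize(ca - nn)
  d <- -row_normalize(u1 + u2)
  nn + GEOM$b_n_h * d
}

# C-beta from (N, CA, C): ideal tetrahedral direction off the N-CA-C plane.
place_cb_rows <- function(A) {
  nn <- A[, 1:3, drop = FALSE]; ca <- A[, 4:6, drop = FALSE]
  cc <- A[, 7:9, drop = FALSE]
  u1 <- row_normalize(nn - ca)
  u2 <- row_normalize(cc - ca)
  dot12 <- row_dot(u1, u2)
  p <- cos(GEOM$a_n_ca_cb) / (1 + dot12)
  # cross(u1, u2) puts the C-beta on the L-amino-acid side (improper
  # dihedral CB-CA-N-C near -123 degrees, as in experimental structures)
  nrm <- row_normalize(row_cross(u1, u2))
  # the out-of-plane component vanishes as the N-CA-C angle opens; a smooth
  # floor keeps the placement finite (and complex-step differentiable) for
  # the strained geometries a hot trajectory can visit transiently
  q2 <- 1 - 2 * p^2 * (1 + dot12)
  q2 <- (q2 + sqrt(q2 * q2 + 1e-12)) / 2
  q <- sqrt(q2)
  d <- p * (u1 + u2) + q * nrm
  ca + GEOM$b_ca_cb * d
}

# local residue frame (ex, ey, ez) from (N, CA, C); returns n x 9.
frame_rows <- function(A) {
  nn <- A[, 1:3, drop = FALSE]; ca <- A[, 4:6, drop = FALSE]
  cc <- A[, 7:9, drop = FALSE]
  ex <- row_normalize(cc - nn)
  t <- ca - (nn + cc) / 2
  ey <- row_normalize(t - row_dot(t, ex) * ex)
  ez <- row_cross(ex, ey)
  cbind(ex, ey, ez)
}

# place a local coordinate (possibly orientation-only) in every residue
# frame; A is n x 9 parent coords, local a length-3 vector (shared by all
# rows) or an n x 3 matrix (one local per row).
place_local_rows <- function(A, local, origin = TRUE) {
  fr <- frame_rows(A)
  if (is.matrix(local)) {
    stopifnot(nrow(local) == nrow(A), ncol(local) == 3)
    l1 <- local[, 1]; l2 <- local[, 2]; l3 <- local[, 3]
  } else {
    l1 <- local[1]; l2 <- local[2]; l3 <- local[3]
  }
  out <- l1 * fr[, 1:3, drop = FALSE] +
    l2 * fr[, 4:6, drop = FALSE] +
    l3 * fr[, 7:9, drop = FALSE]
  if (origin) out <- out + A[, 4:6, drop = FALSE]
  out
}

collinear_check <- function(A) {
  u1 <- row_normalize(A[, 1:3, drop = FALSE] - A[, 4:6, drop = FALSE])
  u2 <- row_normalize(A[, 7:9, drop = FALSE] - A[, 4:6, drop = FALSE])
  s2 <- 1 - row_dot(u1, u2)^2
  if (any(s2 < 1e-12))
    cg_error("cg_geometry_error",
             sprintf("degenerate (collinear) backbone frame at residue %d",
                     which(s2 < 1e-12)[1]))
  invisible(TRUE)
}

#' Place derived virtual sites (O, H, C-beta)
#'
#' The carbonyl oxygen, amide proton and C-beta of every residue are
#' deterministic functions of the three backbone atoms of the owning (and
#' neighboring) residues.  The first residue has no amide proton; the last
#' residue's oxygen uses an extrapolated ideal peptide frame.  Glycine gets a
#' pseudo C-beta at the ideal tetrahedral position so that burial and
#' environment terms are defined for every residue.
#'
#' @param state a [cg_backbone].
#' @param jacobian also compute placement Jacobians (needed for force
#'   pullback; skip for pure geometry queries).
#' @param burial_params burial-count geometry (see [burial_counts()]).
#' @return an object of class `cg_frame` with fields `O`, `H`, `CB`
#'   (`nres` x 3; `H[1, ]` is `NA`), `burial` (smooth neighbor counts) and,
#'   when requested, `jac` (per-site Jacobians plus parent-atom indices).
#' @export
place_virtual_sites <- function(state, jacobian = TRUE,
                                burial_params = BURIAL_DEFAULTS) {
  n <- state$nres
  x <- state$x
  rN <- atom_row(1:n, "N"); rCA <- atom_row(1:n, "CA"); rC <- atom_row(1:n, "C")
  own <- cbind(x[rN, , drop = FALSE], x[rCA, , drop = FALSE],
               x[rC, , drop = FALSE])
  collinear_check(own)

  # O: interior residues use the next N, the last an extrapolated frame.
  O <- matrix(NA_real_, n, 3)
  o_par <- matrix(NA_integer_, n, 3)
  if (n > 1) {
    Ao <- cbind(x[rCA[1:(n - 1)], , drop = FALSE],
                x[rC[1:(n - 1)], , drop = FALSE],
                x[rN[2:n], , drop = FALSE])
    O[1:(n - 1), ] <- place_o_rows(Ao)
    o_par[1:(n - 1), ] <- cbind(rCA[1:(n - 1)], rC[1:(n - 1)], rN[2:n])
  }
  O[n, ] <- place_o_last_rows(own[n, , drop = FALSE])
  o_par[n, ] <- c(rN[n], rCA[n], rC[n])

  # H: all but the first residue.
  H <- matrix(NA_real_, n, 3)
  h_par <- matrix(NA_integer_, n, 3)
  if (n > 1) {
    Ah <- cbind(x[rC[1:(n - 1)], , drop = FALSE],
                x[rN[2:n], , drop = FALSE],
                x[rCA[2:n], , drop = FALSE])
    H[2:n, ] <- place_h_rows(Ah)
    h_par[2:n, ] <- cbind(rC[1:(n - 1)], rN[2:n], rCA[2:n])
  }

  CB <- place_cb_rows(own)
  cb_par <- cbind(rN, rCA, rC)

  frame <- list(O = O, H = H, CB = CB, has_H = c(FALSE, rep(TRUE, n - 1)),
                o_par = o_par, h_par = h_par, cb_par = cb_par, nres = n)

  if (jacobian) {
    JO <- array(0, c(n, 3, 9))
    if (n > 1) JO[1:(n - 1), , ] <- jac_complex(place_o_rows, Ao)
    JO[n, , ] <- jac_complex(place_o_last_rows, own[n, , drop = FALSE])
    JH <- array(0, c(n, 3, 9))
    if (n > 1) JH[2:n, , ] <- jac_complex(place_h_rows, Ah)
    JCB <- jac_complex(place_cb_rows, own)
    frame$jac <- list(O = JO, H = JH, CB = JCB)
  }

  frame$burial_params <- burial_params
  frame$burial <- burial_counts(state, frame, burial_params)
  class(frame) <- "cg_frame"
  frame
}

#' Smooth burial counts
#'
#' For each residue, the approximate number of side chains within a
#' hemisphere above its C-beta: every neighbor C-beta contributes the product
#' of a logistic radial switch (centered `r_center`, width `r_width`) and a
#' logistic hemispherical switch on the cosine of the angle to the
#' C-alpha -> C-beta axis (centered `a_center`, width `a_width`).  The count
#' is real-valued and C1-smooth in all coordinates.
#'
#' @param state a [cg_backbone].
#' @param frame a `cg_frame` from [place_virtual_sites()].
#' @param params list with `r_center`, `r_width`, `a_center`, `a_width`.
#' @return numeric vector of per-residue counts `N_i >= 0`.
#' @export
burial_counts <- function(state, frame, params = BURIAL_DEFAULTS) {
  burial_core(frame$CB, ca_coords(state), params, weights = NULL)$counts
}

# Burial counts and (optionally) the gradient of sum_i w_i * N_i with
# respect to the CB and CA coordinates (w = weights).
burial_core <- function(CB, CA, params, weights = NULL) {
  n <- nrow(CB)
  counts <- numeric(n)
  want_grad <- !is.null(weights)
  gCB <- if (want_grad) matrix(0, n, 3) else NULL
  gCA <- if (want_grad) matrix(0, n, 3) else NULL
  if (n < 2) return(list(counts = counts, gCB = gCB, gCA = gCA))
  axis <- CB - CA
  alen <- sqrt(rowSums(axis^2))
  u <- axis / alen
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    d <- CB[j, , drop = FALSE] - matrix(CB[i, ], length(j), 3, byrow = TRUE)
    r <- sqrt(rowSums(d^2))
    nh <- d / r
    cth <- as.vector(nh %*% u[i, ])
    sr <- logistic_down(r, params$r_center, params$r_width, deriv = want_grad)
    sa <- logistic_up(cth, params$a_center, params$a_width, deriv = want_grad)
    if (!want_grad) {
      counts[i] <- sum(sr * sa)
    } else {
      counts[i] <- sum(sr$value * sa$value)
      w <- weights[i]
      if (w != 0) {
        # d term / d CB_j through r and cos(theta)
        gr <- sr$deriv * sa$value            # coefficient of dr
        gc <- sr$value * sa$deriv            # coefficient of dcos
        dcos_dCBj <- (matrix(u[i, ], length(j), 3, byrow = TRUE) -
                        cth * nh) / r
        gj <- gr * nh + gc * dcos_dCBj
        gCB[j, ] <- gCB[j, ] + w * gj
        gCB[i, ] <- gCB[i, ] - w * colSums(gj)
        # dependence of cos(theta) on the axis u_i
        du <- gc * (nh - cth * matrix(u[i, ], length(j), 3, byrow = TRUE))
        gu <- colSums(du) / alen[i]
        gCB[i, ] <- gCB[i, ] + w * gu
        gCA[i, ] <- gCA[i, ] - w * gu
      }
    }
  }
  list(counts = counts, gCB = gCB, gCA = gCA)
}

#' Pull derived-site gradients back onto the backbone atoms
#'
#' Applies the exact adjoint of the placement maps: gradients on the O, H and
#' C-beta sites are converted, via the placement Jacobians, into gradients on
#' the N, CA and C atoms that generated them.  Linear in the site gradients;
#' a zero site gradient contributes nothing.
#'
#' @param frame a `cg_frame` computed with `jacobian = TRUE`.
#' @param site_grads list with any of `O`, `H`, `CB`: `nres` x 3 gradient
#'   matrices (`NA`-free; use zeros for absent sites).
#' @param grad optional existing `3*nres` x 3 gradient matrix to accumulate
#'   into.
#' @return `3*nres` x 3 matrix of backbone-atom gradients.
#' @export
pullback_gradients <- function(frame, site_grads, grad = NULL) {
  n <- frame$nres
  if (is.null(grad)) grad <- matrix(0, 3 * n, 3)
  if (is.null(frame$jac))
    cg_error("cg_geometry_error", "frame was built without Jacobians")
  pull_one <- function(J, parents, g) {
    for (i in seq_len(n)) {
      if (any(is.na(parents[i, ]))) next
      gi <- g[i, ]
      if (all(gi == 0)) next
      contrib <- gi[1] * J[i, 1, ] + gi[2] * J[i, 2, ] + gi[3] * J[i, 3, ]
      rows <- parents[i, ]
      grad[rows[1], ] <<- grad[rows[1], ] + contrib[1:3]
      grad[rows[2], ] <<- grad[rows[2], ] + contrib[4:6]
      grad[rows[3], ] <<- grad[rows[3], ] + contrib[7:9]
    }
  }
  if (!is.null(site_grads$O)) pull_one(frame$jac$O, frame$o_par, site_grads$O)
  if (!is.null(site_grads$H)) pull_one(frame$jac$H, frame$h_par, site_grads$H)
  if (!is.null(site_grads$CB)) pull_one(frame$jac$CB, frame$cb_par,
                                        site_grads$CB)
  grad
}
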