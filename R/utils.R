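# Small numeric and error helpers shared across the package.

cg_error <- function(class, msg, ...) {
  data <- list(...)
  cond <- structure(
    class = c(class, "cg_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compactly supported C1 switching functions
#'
#' `switch_down()` is 1 for `x <= c - w`, 0 for `x >= c + w`, and follows the
#' cubic smoothstep in between; `switch_up()` is its mirror image.  Both
#' return the value and, via `deriv = TRUE`, the derivative.  Used wherever a
#' term must vanish *exactly* beyond a cutoff (hydrogen bonds, sterics).
#'
#' @param x numeric vector of evaluation points.
#' @param center,width switch center and half-width (same units as `x`).
#' @param deriv if `TRUE` return `list(value, deriv)`.
#' @return numeric vector, or a list with elements `value` and `deriv`.
#' @keywords internal
switch_down <- function(x, center, width, deriv = FALSE) {
  t <- (center + width - x) / (2 * width)
  t <- pmin(pmax(t, 0), 1)
  v <- t * t * (3 - 2 * t)
  if (!deriv) return(v)
  inside <- t > 0 & t < 1
  dv <- numeric(length(x))
  dv[inside] <- -(6 * t[inside] * (1 - t[inside])) / (2 * width)
  list(value = v, deriv = dv)
}

#' @rdname switch_down
#' @keywords internal
switch_up <- function(x, center, width, deriv = FALSE) {
  s <- switch_down(x, center, width, deriv = deriv)
  if (!deriv) return(1 - s)
  list(value = 1 - s$value, deriv = -s$deriv)
}

# Logistic switches (never exactly zero); used for the smooth burial count.
logistic_down <- function(x, center, width, deriv = FALSE) {
  z <- (x - center) / width
  v <- 1 / (1 + exp(z))
  if (!deriv) return(v)
  list(value = v, deriv = -v * (1 - v) / width)
}

logistic_up <- function(x, center, width, deriv = FALSE) {
  s <- logistic_down(x, center, width, deriv = deriv)
  if (!deriv) return(1 - s)
  list(value = 1 - s$value, deriv = -s$deriv)
}

# Row-wise helpers for m x 3 matrices (complex-safe: no abs/Re involved).
row_dot <- function(a, b) a[, 1] * b[, 1] + a[, 2] * b[, 2] + a[, 3] * b[, 3]
row_norm <- function(a) sqrt(row_dot(a, a))
row_normalize <- function(a) a / row_norm(a)
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Rotation matrix about a unit axis (Rodrigues).
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * c + s * ux + (1 - c) * (u %o% u)
}

# Natural extension reference frame (NeRF): place atom D given A,B,C with
# bond length |C-D|, angle B-C-D and torsion A-B-C-D.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * n
}

# Dihedral angle over four points (rows of a matrix or four 3-vectors).
dihedral_angle <- function(r1, r2, r3, r4) {
  b1 <- r2 - r1; b2 <- r3 - r2; b3 <- r4 - r3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  b2n <- b2 / sqrt(sum(b2^2))
  atan2(sum(m1 * b2n), sum(n1 * n2))
}

# Dihedral angle and its gradient with respect to the four atoms.
# Standard rigid-rotation formulas; the four gradients sum to zero.
dihedral_grad <- function(r1, r2, r3, r4) {
  b1 <- r2 - r1; b2 <- r3 - r2; b3 <- r4 - r3
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  phi <- atan2(sum(cross3(n1, n2) * (b2 / nb2)), sum(n1 * n2))
  g1 <- -(nb2 / sum(n1^2)) * n1
  g4 <- (nb2 / sum(n2^2)) * n2
  c12 <- sum(b1 * b2) / sum(b2^2)
  c32 <- sum(b3 * b2) / sum(b2^2)
  g2 <- -(1 + c12) * g1 + c32 * g4
  g3 <- c12 * g1 - (1 + c32) * g4
  list(angle = phi, g = rbind(g1, g2, g3, g4))
}

# Bond angle a-b-c and gradient with respect to the three atoms.
angle_grad <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  cth <- sum(u * v) / (nu * nv)
  cth <- max(min(cth, 1), -1)
  th <- acos(cth)
  s <- sqrt(max(1 - cth^2, 1e-12))
  ga <- (cth * u / nu - v / nv) / (nu * s)
  gc <- (cth * v / nv - u / nu) / (nv * s)
  gb <- -(ga + gc)
  list(angle = th, g = rbind(ga, gb, gc))
}

# Gradient of the unit vector (b - a)/|b - a| contracted with a vector g:
# returns d(g . nhat)/da and /db.  Used for derived site orientations.
unit_vec_chain <- function(a, b, g) {
  d <- b - a
  r <- sqrt(sum(d^2))
  nhat <- d / r
  gb <- (g - sum(g * nhat) * nhat) / r
  list(ga = -gb, gb = gb)
}

wrap_angle <- function(x) {
  # wrap to (-pi, pi]
  y <- (x + pi) %% (2 * pi)
  y - pi
}
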