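#' Uniform cubic B-spline curves with trainable coefficients
#'
#' All tunable interaction curves in the force field (radial and angular pair
#' curves, environment/burial curves) are uniform cubic B-splines.  The curve
#' value is linear in its coefficients, so the derivative of any energy with
#' respect to the coefficients is simply the vector of basis-function values
#' at the evaluation points.
#'
#' With `zero_tail = TRUE` (radial curves) three phantom coefficients beyond
#' the upper end of the domain are pinned to zero, so the curve value and all
#' derivatives vanish identically at and beyond the cutoff.  Evaluation
#' outside the domain is clamped with zero slope at the lower end (and, for
#' `zero_tail = FALSE`, at both ends).
#'
#' @param coef numeric vector of free coefficients (trainable).
#' @param lo,hi domain limits.
#' @param zero_tail logical: pin the curve to zero at and beyond `hi`.
#' @return an object of class `cg_spline`.
#' @examples
#' s <- spline_curve(rnorm(16), 0, 10, zero_tail = TRUE)
#' spline_eval(s, c(2.5, 9.99, 10, 12))$value
#' @export
spline_curve <- function(coef, lo, hi, zero_tail = FALSE) {
  if (length(coef) < 4)
    cg_error("cg_spline_error", "a cubic spline needs at least 4 coefficients")
  if (!(hi > lo))
    cg_error("cg_spline_error", "spline domain must have hi > lo")
  n <- length(coef)
  m <- if (zero_tail) n else n - 3L   # number of knot intervals
  structure(list(coef = as.numeric(coef), lo = lo, hi = hi,
                 n = n, m = m, h = (hi - lo) / m, zero_tail = zero_tail),
            class = "cg_spline")
}

# Cubic B-spline segment values for local coordinate t in [0,1):
# weights of coefficients (i, i+1, i+2, i+3) when u = i + t.
bspline_w <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind((1 - 3 * t + 3 * t2 - t3) / 6,
        (4 - 6 * t2 + 3 * t3) / 6,
        (1 + 3 * t + 3 * t2 - 3 * t3) / 6,
        t3 / 6)
}

bspline_dw <- function(t) {
  t2 <- t * t
  cbind((-3 + 6 * t - 3 * t2) / 6,
        (-12 * t + 9 * t2) / 6,
        (3 + 6 * t - 9 * t2) / 6,
        3 * t2 / 6)
}

#' Evaluate a spline curve
#'
#' @param s a [spline_curve()].
#' @param x numeric vector of evaluation points.
#' @param basis if `TRUE`, also return the dense basis matrix
#'   (`length(x)` rows by `length(s$coef)` columns) giving the exact
#'   derivative of each value with respect to each coefficient.
#' @return list with `value`, `deriv` (d value / d x) and optionally `basis`.
#' @export
spline_eval <- function(s, x, basis = FALSE) {
  x0 <- x
  # clamp with zero slope outside the domain (value continues flat);
  # for zero-tail curves the value at the upper end is already 0.
  xl <- pmin(pmax(x, s$lo), s$hi)
  u <- (xl - s$lo) / s$h
  i <- pmin(floor(u), s$m - 1)
  t <- u - i
  W <- bspline_w(t)
  D <- bspline_dw(t) / s$h
  # coefficient index of the first of the four contributors (1-based);
  # phantom indices > n carry coefficient zero.
  idx <- outer(i, 0:3, "+") + 1L
  cf <- c(s$coef, 0, 0, 0)
  val <- rowSums(W * matrix(cf[idx], nrow = length(x)))
  der <- rowSums(D * matrix(cf[idx], nrow = length(x)))
  outside <- x0 < s$lo | x0 > s$hi
  der[outside] <- 0
  out <- list(value = val, deriv = der)
  if (basis) {
    B <- matrix(0, length(x), s$n)
    keep <- idx <= s$n
    B[cbind(rep(seq_along(x), 4)[keep], idx[keep])] <- W[keep]
    out$basis <- B
  }
  out
}

#' @export
print.cg_spline <- function(x, ...) {
  cat(sprintf("<cg_spline: %d coefficients on [%g, %g]%s>\n",
              x$n, x$lo, x$hi, if (x$zero_tail) ", zero tail" else ""))
  invisible(x)
}
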