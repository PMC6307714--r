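# The trainable parameter set and its bookkeeping.
#
# Trainable blocks (in the documented flattening order):
#   1. 210 side-chain pair types (unordered amino-acid pairs), each with a
#      scale kappa and 62 spline coefficients: radial 16 + angular 16 on
#      [0, 10 A] (zero tail) and ang1 15 + ang2 15 on [-1, 1].
#   2. 100 backbone-site pairs (5 sites x 20 residue types), each with kappa
#      and 54 coefficients: 14 + 14 on [0, 8 A] and 13 + 13 on [-1, 1].
#   3. 20 environment curves over the burial count, 10 coefficients each.
#   4. the Ramachandran beta-sheet bias scalar.
#   5. the hydrogen-bond magnitude scalar.
# Everything else (H-bond geometry, sterics, bonded springs, Ramachandran
# grids) is fixed and never touched by training.

PARAM_DEFAULT_CONFIG <- list(
  sc_cutoff = 10, bb_cutoff = 8,
  sc_n = c(radial = 16L, angular = 16L, ang1 = 15L, ang2 = 15L),
  bb_n = c(radial = 14L, angular = 14L, ang1 = 13L, ang2 = 13L),
  env_n = 10L, env_max = 15,
  rama_n = 24L
)

#' Index of an unordered side-chain pair type
#'
#' Maps two residue codes to the canonical index 1..210 of the unordered
#' pair over the 20 canonical amino acids.  Also returns whether the
#' arguments were swapped to reach canonical order.
#'
#' @param a,b one-letter residue codes.
#' @return list with `index` and `swapped`.
#' @export
sc_pair_index <- function(a, b) {
  ia <- match(a, AA_CODES); ib <- match(b, AA_CODES)
  if (is.na(ia) || is.na(ib))
    cg_error("cg_sequence_error", "unknown residue code in pair type")
  i <- min(ia, ib); j <- max(ia, ib)
  k <- (i - 1L) * 21L - (i * (i - 1L)) %/% 2L + (j - i + 1L)
  list(index = k, swapped = ib < ia)
}

#' @rdname sc_pair_index
#' @param site backbone site ("H", "O", "N", "CA", "C").
#' @export
bb_pair_index <- function(site, a) {
  s <- match(site, BB_SITES); ia <- match(a, AA_CODES)
  if (is.na(s) || is.na(ia))
    cg_error("cg_sequence_error", "unknown backbone site or residue code")
  (s - 1L) * 20L + ia
}

new_pair_params <- function(kappa, radial, angular, ang1, ang2, cutoff) {
  structure(list(
    kappa = kappa,
    radial = spline_curve(radial, 0, cutoff, zero_tail = TRUE),
    angular = spline_curve(angular, 0, cutoff, zero_tail = TRUE),
    ang1 = spline_curve(ang1, -1, 1),
    ang2 = spline_curve(ang2, -1, 1),
    cutoff = cutoff
  ), class = "cg_pair_params")
}

#' Construct a parameter set
#'
#' Builds a full `cg_params` object from raw coefficient blocks; use
#' [make_toy_parameters()] for random-but-valid sets and [read_params()] /
#' [write_params()] for file I/O.  All-zero trainable blocks (the default)
#' make the total energy reduce to the fixed bonded + steric terms.
#'
#' @param sc list of 210 elements `list(kappa, radial, angular, ang1, ang2)`
#'   or `NULL` for zeros.
#' @param bb list of 100 such elements or `NULL`.
#' @param env list of 20 coefficient vectors or `NULL`.
#' @param rama a Ramachandran table list (see [make_rama_table()]) or `NULL`
#'   for the bundled default.
#' @param sheet_bias,hbond_magnitude trainable scalars.
#' @param config spline/cutoff layout (see `PARAM_DEFAULT_CONFIG`).
#' @return an object of class `cg_params`.
#' @export
new_parameter_set <- function(sc = NULL, bb = NULL, env = NULL, rama = NULL,
                              sheet_bias = 0, hbond_magnitude = 0,
                              config = PARAM_DEFAULT_CONFIG) {
  zero_block <- function(n) list(kappa = 1, radial = numeric(n[["radial"]]),
                                 angular = numeric(n[["angular"]]),
                                 ang1 = numeric(n[["ang1"]]),
                                 ang2 = numeric(n[["ang2"]]))
  if (is.null(sc)) sc <- replicate(210, zero_block(config$sc_n),
                                   simplify = FALSE)
  if (is.null(bb)) bb <- replicate(100, zero_block(config$bb_n),
                                   simplify = FALSE)
  if (is.null(env)) env <- replicate(20, numeric(config$env_n),
                                     simplify = FALSE)
  if (length(sc) != 210)
    cg_error("cg_schema_error", "sc_pairs block must have 210 pair types",
             block = "sc_pairs")
  if (length(bb) != 100)
    cg_error("cg_schema_error", "bb_pairs block must have 100 pair types",
             block = "bb_pairs")
  if (length(env) != 20)
    cg_error("cg_schema_error", "env block must have 20 curves",
             block = "env")
  mk <- function(b, n, cutoff) {
    stopifnot(length(b$radial) == n[["radial"]],
              length(b$angular) == n[["angular"]],
              length(b$ang1) == n[["ang1"]],
              length(b$ang2) == n[["ang2"]])
    new_pair_params(b$kappa, b$radial, b$angular, b$ang1, b$ang2, cutoff)
  }
  sc_pp <- lapply(sc, mk, n = config$sc_n, cutoff = config$sc_cutoff)
  bb_pp <- lapply(bb, mk, n = config$bb_n, cutoff = config$bb_cutoff)
  if (any(vapply(env, length, 1L) != config$env_n))
    cg_error("cg_schema_error", "env curve length mismatch", block = "env")
  env_curves <- lapply(env, spline_curve, lo = 0, hi = config$env_max)
  names(env_curves) <- AA_CODES
  if (is.null(rama)) rama <- make_rama_table(n = config$rama_n)
  structure(list(
    sc_pairs = sc_pp, bb_pairs = bb_pp, env = env_curves,
    rama = rama, sheet_bias = sheet_bias,
    hbond = list(magnitude = hbond_magnitude, geom = HBOND_GEOM),
    steric = STERIC_DEFAULTS,
    bonded = list(k_bond = 100, k_angle = 40, k_omega = 10),
    burial = BURIAL_DEFAULTS,
    config = config, version = 1L
  ), class = "cg_params")
}

#' Count parameters by block
#'
#' Reports the structural bookkeeping of a parameter set: the number of
#' side-chain pair types, side-chain spline coefficients, backbone-site
#' spline coefficients, environment-curve coefficients, trainable scalars and
#' pair scale factors.  The default layout gives 210 side-chain pair types
#' with 62 coefficients each (13020) and 100 backbone-site interactions with
#' 54 each (5400).
#'
#' @param pset a `cg_params`.
#' @return named list of integer counts.
#' @export
count_parameters <- function(pset) {
  per_sc <- sum(pset$config$sc_n)
  per_bb <- sum(pset$config$bb_n)
  list(
    sc_pair_types = length(pset$sc_pairs),
    sc_pair_params = length(pset$sc_pairs) * per_sc,
    bb_pair_params = length(pset$bb_pairs) * per_bb,
    env_params = length(pset$env) * pset$config$env_n,
    scalars = 2L,
    kappas = length(pset$sc_pairs) + length(pset$bb_pairs),
    total_trainable = length(flatten_params(pset))
  )
}

#' Flatten the trainable parameters to a vector
#'
#' The ordering is stable and documented: side-chain pair blocks 1..210
#' (kappa, radial, angular, ang1, ang2), backbone pair blocks 1..100 (same
#' layout), environment curves in `AA_CODES` order, then the sheet bias and
#' the hydrogen-bond magnitude.  `unflatten_params()` is its exact inverse.
#'
#' @param pset a `cg_params`.
#' @return numeric vector alpha.
#' @export
flatten_params <- function(pset) {
  blk <- function(pp) c(pp$kappa, pp$radial$coef, pp$angular$coef,
                        pp$ang1$coef, pp$ang2$coef)
  c(unlist(lapply(pset$sc_pairs, blk), use.names = FALSE),
    unlist(lapply(pset$bb_pairs, blk), use.names = FALSE),
    unlist(lapply(pset$env, function(s) s$coef), use.names = FALSE),
    pset$sheet_bias, pset$hbond$magnitude)
}

#' @rdname flatten_params
#' @param alpha numeric vector from [flatten_params()].
#' @export
unflatten_params <- function(pset, alpha) {
  want <- length(flatten_params(pset))
  if (length(alpha) != want)
    cg_error("cg_parameter_mismatch_error",
             sprintf("alpha has length %d, expected %d", length(alpha), want))
  pos <- 0L
  take <- function(k) {
    out <- alpha[(pos + 1L):(pos + k)]
    pos <<- pos + k
    out
  }
  set_blk <- function(pp) {
    pp$kappa <- take(1L)
    pp$radial$coef <- take(pp$radial$n)
    pp$angular$coef <- take(pp$angular$n)
    pp$ang1$coef <- take(pp$ang1$n)
    pp$ang2$coef <- take(pp$ang2$n)
    pp
  }
  pset$sc_pairs <- lapply(pset$sc_pairs, set_blk)
  pset$bb_pairs <- lapply(pset$bb_pairs, set_blk)
  pset$env <- lapply(pset$env, function(s) { s$coef <- take(s$n); s })
  pset$sheet_bias <- take(1L)
  pset$hbond$magnitude <- take(1L)
  pset
}

#' @export
print.cg_params <- function(x, ...) {
  ct <- count_parameters(x)
  cat("<cg_params>\n")
  cat(sprintf("  side-chain pairs : %d types, %d spline coefficients\n",
              ct$sc_pair_types, ct$sc_pair_params))
  cat(sprintf("  backbone pairs   : %d interactions, %d coefficients\n",
              length(x$bb_pairs), ct$bb_pair_params))
  cat(sprintf("  environment      : %d coefficients\n", ct$env_params))
  cat(sprintf("  scalars          : sheet bias %.4g, H-bond magnitude %.4g\n",
              x$sheet_bias, x$hbond$magnitude))
  cat(sprintf("  trainable total  : %d\n", ct$total_trainable))
  invisible(x)
}
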