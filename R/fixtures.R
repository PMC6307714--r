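# Synthetic fixtures: idealized backbones built from (phi, psi) dihedrals,
# random-but-valid parameter sets, and an exactly solvable two-basin toy.
# Everything is seed-deterministic and generated at run time.

# Build an ideal-geometry backbone from per-residue (phi, psi) angles.
build_chain <- function(sequence, phi, psi) {
  n <- length(sequence)
  x <- matrix(0, 3 * n, 3)
  # first residue in a canonical pose
  x[atom_row(1, "N"), ] <- c(0, 0, 0)
  x[atom_row(1, "CA"), ] <- c(GEOM$b_n_ca, 0, 0)
  ang <- GEOM$a_n_ca_c
  x[atom_row(1, "C"), ] <- x[atom_row(1, "CA"), ] +
    GEOM$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      # C_i from phi_i = (C_{i-1}, N_i, CA_i, C_i)
      x[atom_row(i, "C"), ] <- nerf_place(
        x[atom_row(i - 1, "C"), ], x[atom_row(i, "N"), ],
        x[atom_row(i, "CA"), ], GEOM$b_ca_c, GEOM$a_n_ca_c, phi[i])
    }
    if (i < n) {
      # N_{i+1} from psi_i = (N_i, CA_i, C_i, N_{i+1})
      x[atom_row(i + 1, "N"), ] <- nerf_place(
        x[atom_row(i, "N"), ], x[atom_row(i, "CA"), ],
        x[atom_row(i, "C"), ], GEOM$b_c_n, GEOM$a_ca_c_n, psi[i])
      # CA_{i+1} from omega = (CA_i, C_i, N_{i+1}, CA_{i+1}) = pi
      x[atom_row(i + 1, "CA"), ] <- nerf_place(
        x[atom_row(i, "CA"), ], x[atom_row(i, "C"), ],
        x[atom_row(i + 1, "N"), ], GEOM$b_n_ca, GEOM$a_c_n_ca, GEOM$omega)
    }
  }
  new_backbone(sequence, x)
}

# draw (phi, psi) pairs from a Ramachandran grid (probability ~ exp(-E))
sample_rama_angles <- function(n, grid) {
  ng <- nrow(grid)
  h <- 2 * pi / ng
  p <- exp(-as.vector(grid))
  p <- p / sum(p)
  cell <- sample.int(length(p), n, replace = TRUE, prob = p)
  i <- (cell - 1) %% ng          # phi index 0-based
  j <- (cell - 1) %/% ng         # psi index 0-based
  cbind(phi = -pi + (i + stats::runif(n)) * h,
        psi = -pi + (j + stats::runif(n)) * h)
}

#' Generate an idealized backbone fixture
#'
#' Deterministic mini-protein backbones: `helix` uses (phi, psi) =
#' (-57, -47) degrees, `strand` (-120, +130), `coil` samples angles from the
#' bundled Ramachandran table, and `dipeptide` is a 3-residue chain with a
#' single interior (phi, psi).  Optional Gaussian coordinate noise is added
#' after construction.
#'
#' @param kind "helix", "strand", "coil" or "dipeptide".
#' @param nres number of residues (>= 2; `dipeptide` forces 3).
#' @param sequence residue codes; a single code is recycled ("poly-X");
#'   default poly-alanine.
#' @param seed RNG seed (used by coil sampling and noise).
#' @param noise Gaussian coordinate noise amplitude (Angstrom).
#' @param path optional PDB output path.
#' @param rama Ramachandran table for coil sampling (default bundled).
#' @return a [cg_backbone] (invisibly writes `path` when given).
#' @export
make_backbone <- function(kind = c("helix", "strand", "coil", "dipeptide"),
                          nres = 10, sequence = "A", seed = 1, noise = 0,
                          path = NULL, rama = NULL) {
  kind <- match.arg(kind)
  if (kind == "dipeptide") nres <- 3L
  if (length(sequence) == 1) sequence <- rep(sequence, nres)
  sequence <- check_sequence(sequence)
  stopifnot(length(sequence) == nres)
  set.seed(seed)
  d2r <- pi / 180
  ang <- switch(kind,
    helix = cbind(phi = rep(-57 * d2r, nres), psi = rep(-47 * d2r, nres)),
    strand = cbind(phi = rep(-120 * d2r, nres), psi = rep(130 * d2r, nres)),
    dipeptide = cbind(phi = rep(-57 * d2r, nres), psi = rep(-47 * d2r, nres)),
    coil = {
      if (is.null(rama)) rama <- make_rama_table()
      sample_rama_angles(nres, rama$contexts$general)
    })
  st <- build_chain(sequence, ang[, "phi"], ang[, "psi"])
  if (noise > 0)
    st$x <- st$x + matrix(stats::rnorm(length(st$x), sd = noise),
                          nrow(st$x), 3)
  if (!is.null(path)) write_backbone_pdb(st, path)
  st
}

#' Generate a random-but-valid parameter set
#'
#' Smooth random spline coefficients (Gaussian, scaled) for every trainable
#' block, with the radial-curve zero tails enforced by construction.  At
#' `scale = 0` all trainable blocks vanish and the total energy reduces to
#' the fixed bonded + steric terms.
#'
#' @param seed RNG seed.
#' @param scale coefficient scale (energy units); default 0.1 gives gentle,
#'   integration-friendly interactions.
#' @return a `cg_params`.
#' @export
make_toy_parameters <- function(seed = 1, scale = 0.1) {
  stopifnot(scale >= 0)
  set.seed(seed)
  cfg <- PARAM_DEFAULT_CONFIG
  rblk <- function(n) list(kappa = 1,
                           radial = scale * stats::rnorm(n[["radial"]]),
                           angular = scale * stats::rnorm(n[["angular"]]),
                           ang1 = scale * stats::rnorm(n[["ang1"]]),
                           ang2 = scale * stats::rnorm(n[["ang2"]]))
  sc <- replicate(210, rblk(cfg$sc_n), simplify = FALSE)
  bb <- replicate(100, rblk(cfg$bb_n), simplify = FALSE)
  env <- replicate(20, scale * stats::rnorm(cfg$env_n), simplify = FALSE)
  new_parameter_set(sc = sc, bb = bb, env = env,
                    sheet_bias = scale * stats::rnorm(1, sd = 0.1),
                    hbond_magnitude = scale * 5,
                    config = cfg)
}

#' An exactly solvable two-basin toy system
#'
#' One particle in a 1-D double well `V(x) = h (x^2 - 1)^2 + tilt * x`.  The
#' partition function, basin occupancies and energy moments at any
#' temperature are computed by adaptive quadrature, giving an exact Boltzmann
#' reference for sampler tests.
#'
#' @param barrier well depth parameter `h` (barrier height at x = 0).
#' @param tilt linear tilt (0 gives symmetric wells).
#' @return list with `energy(x)`, `force(x)` (= -dV/dx), and
#'   `reference(temperature)` returning `Z`, `p_right` (occupancy of x > 0),
#'   `mean_E` and `var_E`.
#' @export
make_two_basin_toy <- function(barrier = 2, tilt = 0) {
  V <- function(x) barrier * (x^2 - 1)^2 + tilt * x
  dV <- function(x) 4 * barrier * x * (x^2 - 1) + tilt
  reference <- function(temperature) {
    stopifnot(temperature > 0)
    w <- function(x) exp(-V(x) / temperature)
    lim <- 1 + sqrt(sqrt(50 * temperature / barrier) + 1) + 5
    # piecewise quadrature with breakpoints at the wells and the barrier so
    # the adaptive rule resolves arbitrarily narrow wells
    pieces <- function(f, brk) sum(vapply(seq_len(length(brk) - 1),
      function(i) stats::integrate(f, brk[i], brk[i + 1],
                                   rel.tol = 1e-10)$value, 1))
    brk_all <- c(-lim, -1, 0, 1, lim)
    Z <- pieces(w, brk_all)
    Zr <- pieces(w, c(0, 1, lim))
    m1 <- pieces(function(x) V(x) * w(x), brk_all) / Z
    m2 <- pieces(function(x) V(x)^2 * w(x), brk_all) / Z
    list(Z = Z, p_right = Zr / Z, mean_E = m1, var_E = m2 - m1^2)
  }
  list(energy = V, force = function(x) -dV(x), reference = reference,
       barrier = barrier, tilt = tilt)
}
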