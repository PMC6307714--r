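# Langevin (BAOAB) dynamics on the backbone, pivot Monte Carlo moves and
# temperature replica exchange.

#' Thermostat / integrator configuration
#'
#' @param temperature model temperature (T = 1 corresponds to 300 K for
#'   display purposes).
#' @param gamma friction (1/time); `gamma = 0`, `temperature = 0` reduces
#'   BAOAB to velocity Verlet.
#' @param dt timestep (model time units).
#' @param mass uniform atom mass.
#' @return a list used by [langevin_step()].
#' @export
thermostat_config <- function(temperature = 1, gamma = 1, dt = 0.01,
                              mass = 1) {
  stopifnot(temperature >= 0, dt > 0, gamma >= 0, mass > 0)
  list(temperature = temperature, gamma = gamma, dt = dt, mass = mass)
}

#' One BAOAB Langevin step
#'
#' Advances a dynamical state (flat coordinates `x`, momenta `p`, cached
#' force `f = -grad E`) by one step of the BAOAB splitting.  Deterministic
#' given the R random seed.
#'
#' @param dyn list with `x`, `p`, `f` (flat numeric vectors) and `energy`.
#' @param force_provider function(x) -> list(energy, grad).
#' @param config a [thermostat_config()].
#' @return updated `dyn` (with fresh force and energy).
#' @export
langevin_step <- function(dyn, force_provider, config) {
  if (any(!is.finite(dyn$f)))
    cg_error("cg_integration_error",
             sprintf("non-finite force on coordinate %d",
                     which(!is.finite(dyn$f))[1]))
  dt <- config$dt; m <- config$mass
  p <- dyn$p + 0.5 * dt * dyn$f
  x <- dyn$x + 0.5 * dt * p / m
  if (config$gamma > 0) {
    c1 <- exp(-config$gamma * dt)
    c2 <- sqrt((1 - c1^2) * m * config$temperature)
    p <- c1 * p + c2 * stats::rnorm(length(p))
  } else if (config$temperature > 0) {
    # gamma = 0 with T > 0 is plain NVE; nothing to do in the O-block
  }
  x <- x + 0.5 * dt * p / m
  fe <- force_provider(x)
  if (any(!is.finite(fe$grad)))
    cg_error("cg_integration_error",
             sprintf("non-finite force on coordinate %d",
                     which(!is.finite(fe$grad))[1]))
  f <- -fe$grad
  p <- p + 0.5 * dt * f
  list(x = x, p = p, f = f, energy = fe$energy, terms = fe$terms)
}

# initialize a dyn state from flat coordinates
init_dyn <- function(x, force_provider, p = NULL) {
  fe <- force_provider(x)
  list(x = x, p = if (is.null(p)) numeric(length(x)) else p,
       f = -fe$grad, energy = fe$energy, terms = fe$terms)
}

#' Pivot Monte Carlo move
#'
#' Rotates the chain segment C-terminal of a randomly chosen backbone
#' dihedral (phi or psi) by a uniform random angle and accepts with the
#' Metropolis criterion.  Bond lengths and angles are preserved exactly by
#' construction; a rejected move returns the input state unchanged.
#'
#' @param state a [cg_backbone].
#' @param energy_provider function(state) -> scalar energy.
#' @param temperature Metropolis temperature.
#' @param energy current energy of `state` (recomputed if `NULL`).
#' @return list with `state`, `accepted`, `energy`.
#' @export
pivot_move <- function(state, energy_provider, temperature,
                       energy = NULL) {
  n <- state$nres
  stopifnot(n >= 2)
  if (is.null(energy)) energy <- energy_provider(state)
  # choose a dihedral: phi_i (i in 2..n) or psi_i (i in 1..n-1)
  kind <- if (stats::runif(1) < 0.5) "phi" else "psi"
  if (kind == "phi") {
    i <- sample(2:n, 1)
    a1 <- state$x[atom_row(i, "N"), ]; a2 <- state$x[atom_row(i, "CA"), ]
    first_moving <- atom_row(i, "C")
  } else {
    i <- sample(1:(n - 1), 1)
    a1 <- state$x[atom_row(i, "CA"), ]; a2 <- state$x[atom_row(i, "C"), ]
    first_moving <- atom_row(i + 1, "N")
  }
  dang <- stats::runif(1, -pi, pi)
  R <- rotation_about_axis(a2 - a1, dang)
  prop <- state
  rows <- first_moving:nrow(state$x)
  rel <- state$x[rows, , drop = FALSE] -
    matrix(a2, length(rows), 3, byrow = TRUE)
  prop$x[rows, ] <- rel %*% t(R) + matrix(a2, length(rows), 3, byrow = TRUE)
  e_new <- energy_provider(prop)
  accept <- (e_new <= energy) ||
    (temperature > 0 && stats::runif(1) < exp(-(e_new - energy) / temperature))
  if (accept) list(state = prop, accepted = TRUE, energy = e_new)
  else list(state = state, accepted = FALSE, energy = energy)
}

#' Temperature ladder with 1/Nres interval scaling
#'
#' `T_k = T_min + k * base_interval * (nres_ref / nres)`, so the temperature
#' intervals shrink proportionally to 1/Nres, keeping neighbor-swap rates
#' roughly size-independent.
#'
#' @param n_replicas number of replicas.
#' @param t_min lowest (target) temperature.
#' @param base_interval interval at the reference chain length.
#' @param nres chain length; `nres_ref` the normalization anchor.
#' @return list with `temperatures` (strictly increasing) and the inputs.
#' @export
make_ladder <- function(n_replicas, t_min, base_interval = 0.1, nres = 100,
                        nres_ref = 100) {
  stopifnot(n_replicas >= 1, t_min > 0, base_interval >= 0)
  temps <- t_min + (seq_len(n_replicas) - 1) * base_interval *
    (nres_ref / nres)
  list(temperatures = temps, t_min = t_min, base_interval = base_interval,
       nres = nres, nres_ref = nres_ref)
}

#' One replica-exchange sweep
#'
#' Attempts Metropolis swaps between neighboring temperature pairs of one
#' parity (even pairs (1,2), (3,4), ... or odd pairs (2,3), (4,5), ...);
#' alternate the parity between calls.  Swapping exchanges configurations
#' (and their energies) between temperature slots, so the configuration set
#' after a sweep is a permutation of the input.
#'
#' @param configs list of replica configurations (opaque).
#' @param energies numeric vector of current potential energies.
#' @param temperatures ladder temperatures (same length).
#' @param parity "even" or "odd".
#' @return list with permuted `configs`, `energies`, logical `accepted` per
#'   attempted pair and the attempted `pairs`.
#' @export
replica_exchange_step <- function(configs, energies, temperatures,
                                  parity = "even") {
  k <- length(configs)
  stopifnot(length(energies) == k, length(temperatures) == k)
  first <- if (parity == "even") 1L else 2L
  lo <- if (first <= k - 1L) seq(first, k - 1L, by = 2L) else integer(0)
  accepted <- logical(length(lo))
  for (q in seq_along(lo)) {
    a <- lo[q]; b <- a + 1L
    dbeta <- 1 / temperatures[a] - 1 / temperatures[b]
    darg <- dbeta * (energies[a] - energies[b])
    if (darg >= 0 || stats::runif(1) < exp(darg)) {
      tmp <- configs[[a]]; configs[[a]] <- configs[[b]]; configs[[b]] <- tmp
      te <- energies[a]; energies[a] <- energies[b]; energies[b] <- te
      accepted[q] <- TRUE
    }
  }
  list(configs = configs, energies = energies, accepted = accepted,
       pairs = cbind(lo, lo + 1L))
}

#' Hybrid replica-exchange sampler for a backbone system
#'
#' Runs `n_replicas` Langevin replicas at a [make_ladder()] temperature
#' ladder, attempting pivot Monte Carlo moves every `pivot_every` MD steps
#' and neighbor swaps (alternating parity) every `swap_every` steps.  Frames
#' of the target (lowest-temperature) replica are recorded every
#' `record_every` steps.
#'
#' @param state starting [cg_backbone] (all replicas start here).
#' @param pset a `cg_params`.
#' @param steps total MD steps per replica.
#' @param ladder a [make_ladder()] result.
#' @param dt,gamma,mass integrator constants.
#' @param pivot_every,swap_every,record_every period (in steps) of pivot
#'   attempts, swap attempts and frame recording; 0 disables.
#' @param rotlib,sidechain,restraint passed to [make_force_provider()].
#' @return list with `frames` (list of [cg_backbone]), `energies`, `terms`
#'   (matrix), `swap_rate`, `pivot_rate`, `final_states`.
#' @export
simulate_replex <- function(state, pset, steps, ladder,
                            dt = 0.01, gamma = 1, mass = 1,
                            pivot_every = 100L, swap_every = 50L,
                            record_every = 50L, rotlib = NULL,
                            sidechain = TRUE, restraint = NULL) {
  if (sidechain && is.null(rotlib)) rotlib <- default_rotamer_library()
  k <- length(ladder$temperatures)
  providers <- lapply(seq_len(k), function(q)
    make_force_provider(state, pset, temperature = ladder$temperatures[q],
                        rotlib = rotlib, sidechain = sidechain,
                        restraint = restraint))
  dyn <- lapply(seq_len(k), function(q)
    init_dyn(as.vector(state$x), providers[[q]]))
  cfgs <- lapply(ladder$temperatures, function(tt)
    thermostat_config(temperature = tt, gamma = gamma, dt = dt, mass = mass))
  frames <- list()
  energies <- numeric(0)
  terms <- NULL
  parity <- "even"
  n_swap_acc <- 0L; n_swap_try <- 0L
  n_piv_acc <- 0L; n_piv_try <- 0L
  template <- state
  as_state <- function(xflat) {
    st <- template
    st$x <- matrix(xflat, ncol = 3)
    st
  }
  for (step in seq_len(steps)) {
    for (q in seq_len(k))
      dyn[[q]] <- langevin_step(dyn[[q]], providers[[q]], cfgs[[q]])
    if (pivot_every > 0 && step %% pivot_every == 0L) {
      for (q in seq_len(k)) {
        eprov <- function(st) providers[[q]](as.vector(st$x))$energy
        pm <- pivot_move(as_state(dyn[[q]]$x), eprov,
                         ladder$temperatures[q], energy = dyn[[q]]$energy)
        n_piv_try <- n_piv_try + 1L
        if (pm$accepted) {
          n_piv_acc <- n_piv_acc + 1L
          dyn[[q]] <- init_dyn(as.vector(pm$state$x), providers[[q]],
                               p = dyn[[q]]$p)
        }
      }
    }
    if (swap_every > 0 && step %% swap_every == 0L && k >= 2) {
      rx <- replica_exchange_step(dyn, vapply(dyn, `[[`, 1, "energy"),
                                  ladder$temperatures, parity)
      # a swapped configuration keeps its coordinates/forces; momenta are
      # resampled implicitly by the thermostat at the new temperature
      dyn <- rx$configs
      for (q in seq_len(k)) dyn[[q]]$energy <- rx$energies[q]
      n_swap_acc <- n_swap_acc + sum(rx$accepted)
      n_swap_try <- n_swap_try + length(rx$accepted)
      parity <- if (parity == "even") "odd" else "even"
    }
    if (record_every > 0 && step %% record_every == 0L) {
      frames[[length(frames) + 1L]] <- as_state(dyn[[1]]$x)
      energies <- c(energies, dyn[[1]]$energy)
      terms <- rbind(terms, dyn[[1]]$terms)
    }
  }
  list(frames = frames, energies = energies, terms = terms,
       swap_rate = if (n_swap_try) n_swap_acc / n_swap_try else NA_real_,
       pivot_rate = if (n_piv_try) n_piv_acc / n_piv_try else NA_real_,
       final_states = lapply(dyn, function(d) as_state(d$x)))
}
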