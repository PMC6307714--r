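# Contrastive-divergence training: flat-bottom RMSD restraints, restrained
# and free ensemble sampling, and the parameter update
#   delta_alpha = (epsilon / M) * sum_p ( <dV/dalpha>_free - <dV/dalpha>_restrained ).

#' Flat-bottom C-alpha RMSD restraint
#'
#' Specification of a restraint that is exactly zero while the best-fit
#' C-alpha RMSD to a reference stays below `radius`, and grows as
#' `0.5 * k * (RMSD - radius)^2` outside.  It keeps a restrained replica near
#' the reference without biasing the interior of the basin.
#'
#' @param reference a [cg_backbone] or C-alpha matrix.
#' @param radius flat-bottom radius in Angstrom (default 1.0).
#' @param k spring constant in energy units per Angstrom^2 (default 50).
#' @return a `cg_restraint` list.
#' @export
restraint_spec <- function(reference, radius = 1.0, k = 50) {
  stopifnot(radius >= 0, k >= 0)
  structure(list(reference = as_ca_matrix(reference), radius = radius, k = k),
            class = "cg_restraint")
}

#' Evaluate a flat-bottom RMSD restraint
#'
#' Energy and coordinate gradient of a [restraint_spec()].  The gradient uses
#' the envelope theorem for the optimal superposition: with the reference
#' already best-fit onto the current frame, `dRMSD/dx_i =
#' (x_i - y_i) / (n * RMSD)` on the C-alpha rows and zero elsewhere.
#'
#' @param state a [cg_backbone].
#' @param spec a `cg_restraint`.
#' @return list with `energy`, `rmsd`, `grad` (`3*nres` x 3).
#' @export
eval_restraint <- function(state, spec) {
  A <- ca_coords(state)
  n <- nrow(A)
  if (n != nrow(spec$reference))
    cg_error("cg_shape_error",
             sprintf("restraint reference has %d residues, state has %d",
                     nrow(spec$reference), n))
  fit <- kabsch(A, spec$reference)
  diff <- A - fit$aligned_b
  rmsd <- sqrt(mean(rowSums(diff^2)))
  grad <- matrix(0, 3 * state$nres, 3)
  energy <- 0
  if (rmsd > spec$radius && spec$k > 0) {
    excess <- rmsd - spec$radius
    energy <- 0.5 * spec$k * excess^2
    grad[atom_row(1:n, "CA"), ] <- spec$k * excess / (n * rmsd) * diff
  }
  list(energy = energy, rmsd = rmsd, grad = grad)
}

#' Sample an ensemble and its mean parameter derivatives
#'
#' Runs the replica-exchange sampler from `state`, discards the initial
#' `discard_fraction` of recorded target-replica frames as equilibration, and
#' recomputes `dV/dalpha` exactly on each retained frame.  With a `restraint`
#' this produces the restrained (near-native) ensemble; without it the free
#' ensemble.  Restraint energy never contributes to `dV/dalpha` (it has no
#' trainable parameters).
#'
#' @param state starting [cg_backbone].
#' @param pset a `cg_params`.
#' @param steps MD steps per replica.
#' @param ladder a [make_ladder()] result (default: 3 replicas from T = 1).
#' @param restraint optional [restraint_spec()].
#' @param discard_fraction equilibration fraction of recorded frames.
#' @param record_every,pivot_every,swap_every,dt,gamma,mass passed to
#'   [simulate_replex()].
#' @param rotlib,sidechain passed through; `sidechain = FALSE` trains only
#'   backbone-level terms.
#' @param seed optional RNG seed for this sampling run.
#' @return list with `frames`, `energies`, `dalpha` (frames x n_params
#'   matrix), `dalpha_mean`, `mean_rmsd` (to the restraint reference, if
#'   any), `swap_rate`, `pivot_rate`.
#' @export
sample_ensemble <- function(state, pset, steps = 500L, ladder = NULL,
                            restraint = NULL, discard_fraction = 1 / 3,
                            record_every = 25L, pivot_every = 100L,
                            swap_every = 50L, dt = 0.01, gamma = 1, mass = 1,
                            rotlib = NULL, sidechain = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ladder))
    ladder <- make_ladder(3, t_min = 1, base_interval = 0.1,
                          nres = state$nres, nres_ref = 100)
  if (sidechain && is.null(rotlib)) rotlib <- default_rotamer_library()
  record_every <- max(1L, min(as.integer(record_every), as.integer(steps)))
  sim <- simulate_replex(state, pset, steps = steps, ladder = ladder,
                         dt = dt, gamma = gamma, mass = mass,
                         pivot_every = pivot_every, swap_every = swap_every,
                         record_every = record_every, rotlib = rotlib,
                         sidechain = sidechain, restraint = restraint)
  nf <- length(sim$frames)
  stopifnot(nf >= 1)
  keep <- (min(floor(nf * discard_fraction), nf - 1L) + 1L):nf
  frames <- sim$frames[keep]
  dal <- t(vapply(frames, function(f)
    total_energy(f, pset, temperature = ladder$t_min, rotlib = rotlib,
                 sidechain = sidechain, want_dalpha = TRUE)$dalpha,
    numeric(length(flatten_params(pset)))))
  mean_rmsd <- if (is.null(restraint)) NA_real_ else
    mean(vapply(frames, function(f) eval_restraint(f, restraint)$rmsd, 1))
  list(frames = frames, energies = sim$energies[keep], dalpha = dal,
       dalpha_mean = colMeans(dal), mean_rmsd = mean_rmsd,
       swap_rate = sim$swap_rate, pivot_rate = sim$pivot_rate)
}

#' One contrastive-divergence parameter update
#'
#' The core update on a flat parameter vector:
#' `alpha + (epsilon / M) * sum_p (g_free[p, ] - g_restrained[p, ])`, where
#' each row holds the ensemble-mean `dV/dalpha` for one system of the
#' minibatch.  This moves probability mass from the free ensemble toward the
#' restrained (data-like) ensemble.  Also usable on scalar toy models.
#'
#' @param alpha flat parameter vector.
#' @param g_free,g_restrained mean-derivative matrices (`M` x `length(alpha)`)
#'   or vectors (taken as `M = 1`).
#' @param epsilon step size.
#' @return updated flat parameter vector.
#' @export
cd_update <- function(alpha, g_free, g_restrained, epsilon) {
  if (is.null(dim(g_free))) g_free <- matrix(g_free, nrow = 1)
  if (is.null(dim(g_restrained))) g_restrained <- matrix(g_restrained,
                                                         nrow = 1)
  if (ncol(g_free) != length(alpha) || ncol(g_restrained) != length(alpha) ||
      nrow(g_free) != nrow(g_restrained))
    cg_error("cg_parameter_mismatch_error",
             sprintf(paste0("derivative shapes (%d x %d, %d x %d) do not ",
                            "match %d parameters"),
                     nrow(g_free), ncol(g_free), nrow(g_restrained),
                     ncol(g_restrained), length(alpha)))
  alpha + (epsilon / nrow(g_free)) * colSums(g_free - g_restrained)
}

# fixed minibatch partition: ceiling(N / M) batches, assigned round-robin
# after one seeded shuffle so every pass sees the same partition
make_minibatches <- function(n_systems, minibatch_size, seed) {
  set.seed(seed)
  ord <- sample.int(n_systems)
  nb <- ceiling(n_systems / minibatch_size)
  unname(split(ord, rep(seq_len(nb), length.out = n_systems)))
}

# deterministic per-step seed derived from the base seed (kept below 2^31)
derive_seed <- function(seed, step, salt = 0L) {
  (as.double(seed) + 10007 * step + 97 * salt) %% 2147483647
}

#' Contrastive-divergence training loop
#'
#' Trains a parameter set against a set of native backbones.  Each update
#' processes one minibatch: for every system it samples a restrained ensemble
#' (flat-bottom RMSD restraint around the native) and a free ensemble, both
#' started from the native structure, and applies [cd_update()].  The step
#' size is divided by 4 after every `decay_passes` full passes through the
#' data.  The minibatch partition is fixed across passes, and every
#' sampling run gets a seed derived deterministically from `seed` and the
#' global step counter, so training can be resumed reproducibly.
#'
#' @param natives list of native [cg_backbone] structures.
#' @param pset starting `cg_params`.
#' @param n_updates number of minibatch updates.
#' @param minibatch_size systems per update (capped at `length(natives)`).
#' @param epsilon initial step size.
#' @param decay_passes passes between step-size divisions (default 2).
#' @param decay_factor multiplicative decay (default 1/4).
#' @param restraint_radius,restraint_k flat-bottom restraint constants.
#' @param steps,ladder,record_every,discard_fraction,pivot_every,swap_every,
#'   dt,gamma,mass,rotlib,sidechain sampling options, see [sample_ensemble()].
#' @param seed base RNG seed (< 2^31).
#' @param start_step resume from this global step (1-based); with identical
#'   inputs and `pset` equal to the checkpointed parameters this reproduces
#'   an uninterrupted run exactly.
#' @param callback optional function(fit_row, pset) called after each update.
#' @return a `cd_fit`: list with final `params`, `history` data frame
#'   (step, pass, epsilon, grad_norm, mean restrained/free RMSD proxy),
#'   `alpha` (flat), and the configuration used.
#' @export
train_cd <- function(natives, pset, n_updates = 10L, minibatch_size = 12L,
                     epsilon = 0.1, decay_passes = 2L, decay_factor = 0.25,
                     restraint_radius = 1.0, restraint_k = 50,
                     steps = 200L, ladder = NULL, record_every = 25L,
                     discard_fraction = 1 / 3, pivot_every = 100L,
                     swap_every = 50L, dt = 0.01, gamma = 1, mass = 1,
                     rotlib = NULL, sidechain = TRUE, seed = 1L,
                     start_step = 1L, callback = NULL) {
  stopifnot(length(natives) >= 1, n_updates >= 0, epsilon > 0,
            seed < 2^31)
  minibatch_size <- min(minibatch_size, length(natives))
  batches <- make_minibatches(length(natives), minibatch_size, seed)
  nb <- length(batches)
  if (sidechain && is.null(rotlib)) rotlib <- default_rotamer_library()
  alpha <- flatten_params(pset)
  history <- NULL
  last_step <- start_step + n_updates - 1L
  for (step in seq(start_step, length.out = n_updates)) {
    pass <- (step - 1L) %/% nb            # completed passes before this step
    eps_t <- epsilon * decay_factor^(pass %/% decay_passes)
    batch <- batches[[((step - 1L) %% nb) + 1L]]
    g_free <- matrix(0, length(batch), length(alpha))
    g_rest <- matrix(0, length(batch), length(alpha))
    rmsd_rest <- numeric(length(batch))
    for (q in seq_along(batch)) {
      native <- natives[[batch[q]]]
      restr <- restraint_spec(native, radius = restraint_radius,
                              k = restraint_k)
      er <- sample_ensemble(native, pset, steps = steps, ladder = ladder,
                            restraint = restr,
                            discard_fraction = discard_fraction,
                            record_every = record_every,
                            pivot_every = pivot_every,
                            swap_every = swap_every, dt = dt, gamma = gamma,
                            mass = mass, rotlib = rotlib,
                            sidechain = sidechain,
                            seed = derive_seed(seed, step, salt = 2L * q))
      ef <- sample_ensemble(native, pset, steps = steps, ladder = ladder,
                            restraint = NULL,
                            discard_fraction = discard_fraction,
                            record_every = record_every,
                            pivot_every = pivot_every,
                            swap_every = swap_every, dt = dt, gamma = gamma,
                            mass = mass, rotlib = rotlib,
                            sidechain = sidechain,
                            seed = derive_seed(seed, step, salt = 2L * q + 1L))
      g_rest[q, ] <- er$dalpha_mean
      g_free[q, ] <- ef$dalpha_mean
      rmsd_rest[q] <- er$mean_rmsd
    }
    alpha <- cd_update(alpha, g_free, g_rest, eps_t)
    pset <- unflatten_params(pset, alpha)
    row <- data.frame(step = step, pass = pass + 1L, epsilon = eps_t,
                      grad_norm = sqrt(sum(colMeans(g_free - g_rest)^2)),
                      mean_restrained_rmsd = mean(rmsd_rest))
    history <- rbind(history, row)
    if (!is.null(callback)) callback(row, pset)
  }
  structure(list(params = pset, alpha = alpha, history = history,
                 config = list(n_updates = n_updates, last_step = last_step,
                               minibatch_size = minibatch_size,
                               epsilon = epsilon, decay_passes = decay_passes,
                               decay_factor = decay_factor,
                               n_systems = length(natives), seed = seed,
                               steps = steps, sidechain = sidechain)),
            class = "cd_fit")
}

#' @export
print.cd_fit <- function(x, ...) {
  cat("<cd_fit> contrastive-divergence fit\n")
  cat(sprintf("  systems: %d, updates: %d (minibatch %d), seed %s\n",
              x$config$n_systems, x$config$n_updates,
              x$config$minibatch_size, format(x$config$seed)))
  if (!is.null(x$history) && nrow(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  final step %d: epsilon %.4g, grad norm %.4g\n",
                h$step, h$epsilon, h$grad_norm))
    if (is.finite(h$mean_restrained_rmsd))
      cat(sprintf("  mean restrained RMSD %.3f A\n", h$mean_restrained_rmsd))
  }
  invisible(x)
}

#' @export
coef.cd_fit <- function(object, ...) object$alpha
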