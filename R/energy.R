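#' Total energy, forces and parameter derivatives
#'
#' Composes the full coarse-grained energy: fixed bonded and steric terms,
#' the Ramachandran term with sheet bias, backbone hydrogen bonding, the
#' burial-dependent environment potential, and the side-chain Bethe free
#' energy from belief propagation.  The coordinate gradient is assembled by
#' pulling every derived-site contribution (O, H, C-beta, beads) back onto
#' the backbone N, CA, C atoms; the parameter gradient follows the
#' [flatten_params()] ordering.
#'
#' @param state a [cg_backbone].
#' @param pset a `cg_params`.
#' @param temperature temperature used for the side-chain free energy.
#' @param rotlib rotamer library; defaults to [default_rotamer_library()].
#' @param sidechain include the belief-propagation side-chain term.
#' @param want_dalpha also compute the exact parameter gradient.
#' @param bp_init optional warm-start messages from a previous evaluation.
#' @param bp_control list overriding `damping`, `tol`, `max_iter` of
#'   [run_bp()].
#' @return list with `energy`, named `terms`, `grad` (`3*nres` x 3),
#'   `dalpha` (or `NULL`), `beliefs`, `frame` and `bp_init` for warm starts.
#' @export
total_energy <- function(state, pset, temperature = 1, rotlib = NULL,
                         sidechain = TRUE, want_dalpha = FALSE,
                         bp_init = NULL, bp_control = list()) {
  n <- state$nres
  frame <- place_virtual_sites(state, jacobian = TRUE,
                               burial_params = pset$burial)
  grad <- matrix(0, 3 * n, 3)
  site <- list(O = matrix(0, n, 3), H = matrix(0, n, 3),
               CB = matrix(0, n, 3))
  dalpha <- if (want_dalpha) numeric(length(flatten_params(pset))) else NULL
  off <- if (want_dalpha) alpha_offsets(pset) else NULL

  bonded <- eval_bonded(state, pset$bonded)
  grad <- grad + bonded$grad

  steric <- eval_steric(state, frame, pset$steric)
  grad <- grad + steric$grad
  site$CB <- site$CB + steric$gCB

  rama <- rama_term(state, pset)
  grad <- grad + rama$grad
  if (want_dalpha) dalpha[off$bias_pos] <- dalpha[off$bias_pos] + rama$dbias

  hb <- eval_hbond(pset, state, frame)
  grad <- grad + hb$grad
  site$O <- site$O + hb$gO
  site$H <- site$H + hb$gH
  if (want_dalpha) dalpha[off$mag_pos] <- dalpha[off$mag_pos] + hb$dmagnitude

  env <- eval_env(pset, frame$burial, state$seq, want_param = want_dalpha)
  if (any(env$dN != 0)) {
    bc <- burial_core(frame$CB, ca_coords(state), pset$burial,
                      weights = env$dN)
    site$CB <- site$CB + bc$gCB
    rCA <- atom_row(1:n, "CA")
    grad[rCA, ] <- grad[rCA, ] + bc$gCA
  }
  if (want_dalpha) {
    for (a in unique(state$seq)) {
      sel <- which(state$seq == a)
      o <- off$env_start + (match(a, AA_CODES) - 1L) * off$env_len
      dalpha[(o + 1):(o + off$env_len)] <-
        dalpha[(o + 1):(o + off$env_len)] +
        colSums(env$basis[sel, , drop = FALSE])
    }
  }

  beliefs <- NULL
  sc_free <- 0
  bp_out <- NULL
  if (sidechain) {
    if (is.null(rotlib)) rotlib <- default_rotamer_library()
    graph <- build_rotamer_graph(state, frame, pset, rotlib,
                                 temperature = temperature,
                                 want_grad = TRUE, want_param = want_dalpha)
    ctrl <- utils::modifyList(list(damping = 0.5, tol = 1e-12,
                                   max_iter = 200L), bp_control)
    beliefs <- run_bp(graph, temperature, damping = ctrl$damping,
                      tol = ctrl$tol, max_iter = ctrl$max_iter,
                      init = bp_init)
    if (!beliefs$converged)
      warning("belief propagation did not converge; using current beliefs")
    sc_free <- beliefs$free_energy
    fr <- sidechain_forces(graph, beliefs, state, frame,
                           dalpha = dalpha, pset = if (want_dalpha) pset)
    grad <- grad + fr$grad
    site$O <- site$O + fr$site_grads$O
    site$H <- site$H + fr$site_grads$H
    site$CB <- site$CB + fr$site_grads$CB
    if (want_dalpha) dalpha <- fr$dalpha
    bp_out <- beliefs$lmsg
  }

  grad <- pullback_gradients(frame, site, grad = grad)

  terms <- c(bonded = bonded$energy, steric = steric$energy,
             rama = rama$energy, hbond = hb$energy, env = env$energy,
             sidechain = sc_free)
  list(energy = sum(terms), terms = terms, grad = grad, dalpha = dalpha,
       beliefs = beliefs, frame = frame, bp_init = bp_out)
}

#' Energy/force provider for the integrator
#'
#' Wraps [total_energy()] (plus an optional restraint) as a closure mapping a
#' flat coordinate vector to energy and gradient, carrying warm-start
#' messages for belief propagation between calls.
#'
#' @param state template [cg_backbone] (sequence and layout).
#' @param pset a `cg_params`.
#' @param temperature side-chain temperature.
#' @param rotlib rotamer library.
#' @param sidechain include the side-chain term.
#' @param restraint optional [restraint_spec()] applied to the C-alphas.
#' @return function(xflat) -> list(energy, grad) with `grad` flat.
#' @export
make_force_provider <- function(state, pset, temperature = 1, rotlib = NULL,
                                sidechain = TRUE, restraint = NULL) {
  if (sidechain && is.null(rotlib)) rotlib <- default_rotamer_library()
  warm <- NULL
  template <- state
  function(xflat) {
    st <- template
    st$x <- matrix(xflat, ncol = 3, byrow = FALSE)
    te <- total_energy(st, pset, temperature = temperature, rotlib = rotlib,
                       sidechain = sidechain, bp_init = warm)
    warm <<- te$bp_init
    e <- te$energy
    g <- te$grad
    if (!is.null(restraint)) {
      re <- eval_restraint(st, restraint)
      e <- e + re$energy
      g <- g + re$grad
    }
    list(energy = e, grad = as.vector(g), terms = te$terms)
  }
}
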