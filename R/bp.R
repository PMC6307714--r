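# Sum-product belief propagation on the rotamer graph, the Bethe free
# energy, and side-chain forces at the Bethe stationary point.

logsumexp <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}

#' Run belief propagation on a rotamer graph
#'
#' Damped synchronous sum-product message passing in the log domain until the
#' maximum absolute message change falls below `tol` (or `max_iter` sweeps).
#' On tree-structured graphs the resulting marginals and Bethe free energy
#' are exact; on loopy graphs they are the standard Bethe approximation.
#'
#' @param graph a `cg_rotamer_graph` (or any list with fields `n`,
#'   `nstates`, `node_e`, `edges`, `edge_e`).
#' @param temperature temperature `T > 0` (model units).
#' @param damping linear damping of log-messages in `[0, 1)`.
#' @param tol convergence tolerance on the max log-message change.
#' @param max_iter maximum number of synchronous sweeps.
#' @param init optional warm-start log-messages from a previous call (field
#'   `lmsg` of an earlier result).
#' @return object of class `cg_beliefs`: node marginals (list), edge
#'   marginals (list of matrices), `free_energy` (Bethe, energy units),
#'   `converged`, `iterations`, and `lmsg` for warm starts.
#' @export
run_bp <- function(graph, temperature = 1, damping = 0.5, tol = 1e-12,
                   max_iter = 200L, init = NULL) {
  if (temperature <= 0)
    cg_error("cg_bp_error", "temperature must be positive")
  T <- temperature
  n <- graph$n
  ne <- if (is.null(graph$edges)) 0L else nrow(graph$edges)
  phi <- lapply(graph$node_e, function(e) -e / T)   # log node factors

  if (ne == 0L) {
    node_m <- lapply(phi, function(lp) {
      p <- exp(lp - logsumexp(lp)); p / sum(p)
    })
    F <- -T * sum(vapply(phi, logsumexp, 1))
    return(structure(list(node_marginals = node_m, edge_marginals = list(),
                          free_energy = F, converged = TRUE, iterations = 0L,
                          lmsg = NULL),
                     class = "cg_beliefs"))
  }

  lpsi <- lapply(graph$edge_e, function(E) -E / T)  # log edge factors
  # directed messages: msg_fw[[e]] is i->j (length nstates[j]),
  # msg_bw[[e]] is j->i (length nstates[i]) for edge e = (i, j)
  zero_m <- function(k) numeric(graph$nstates[k])
  # a warm start is only usable if the edge set (and state counts) match
  init_ok <- !is.null(init) && length(init$fw) == ne &&
    length(init$bw) == ne &&
    (ne == 0L ||
       (all(lengths(init$fw) == graph$nstates[graph$edges[, 2]]) &&
        all(lengths(init$bw) == graph$nstates[graph$edges[, 1]])))
  if (init_ok) {
    msg_fw <- init$fw; msg_bw <- init$bw
  } else {
    msg_fw <- lapply(seq_len(ne), function(e) zero_m(graph$edges[e, 2]))
    msg_bw <- lapply(seq_len(ne), function(e) zero_m(graph$edges[e, 1]))
  }
  nbr_in <- function(msgs_f, msgs_b) {
    # sum of incoming log-messages at every node
    tot <- lapply(seq_len(n), function(i) numeric(graph$nstates[i]))
    for (e in seq_len(ne)) {
      i <- graph$edges[e, 1]; j <- graph$edges[e, 2]
      tot[[j]] <- tot[[j]] + msgs_f[[e]]
      tot[[i]] <- tot[[i]] + msgs_b[[e]]
    }
    tot
  }
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    tot <- nbr_in(msg_fw, msg_bw)
    delta <- 0
    new_fw <- msg_fw; new_bw <- msg_bw
    for (e in seq_len(ne)) {
      i <- graph$edges[e, 1]; j <- graph$edges[e, 2]
      pre_i <- phi[[i]] + tot[[i]] - msg_bw[[e]]
      pre_j <- phi[[j]] + tot[[j]] - msg_fw[[e]]
      mf <- apply(lpsi[[e]] + pre_i, 2, logsumexp)   # i -> j
      mb <- apply(t(lpsi[[e]]) + pre_j, 2, logsumexp) # j -> i
      mf <- mf - max(mf)
      mb <- mb - max(mb)
      mf <- (1 - damping) * mf + damping * msg_fw[[e]]
      mb <- (1 - damping) * mb + damping * msg_bw[[e]]
      delta <- max(delta, max(abs(mf - msg_fw[[e]])), max(abs(mb - msg_bw[[e]])))
      new_fw[[e]] <- mf; new_bw[[e]] <- mb
    }
    msg_fw <- new_fw; msg_bw <- new_bw
    if (delta < tol) { converged <- TRUE; break }
  }

  tot <- nbr_in(msg_fw, msg_bw)
  node_m <- lapply(seq_len(n), function(i) {
    lp <- phi[[i]] + tot[[i]]
    p <- exp(lp - logsumexp(lp))
    p / sum(p)
  })
  edge_m <- lapply(seq_len(ne), function(e) {
    i <- graph$edges[e, 1]; j <- graph$edges[e, 2]
    pre_i <- phi[[i]] + tot[[i]] - msg_bw[[e]]
    pre_j <- phi[[j]] + tot[[j]] - msg_fw[[e]]
    lb <- lpsi[[e]] + outer(pre_i, pre_j, "+")
    b <- exp(lb - logsumexp(as.vector(lb)))
    b / sum(b)
  })

  # Bethe free energy from converged beliefs
  xlogx <- function(p) sum(ifelse(p > 0, p * log(p), 0))
  deg <- tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = n)
  U <- sum(vapply(seq_len(n), function(i)
    sum(node_m[[i]] * graph$node_e[[i]]), 1)) +
    sum(vapply(seq_len(ne), function(e)
      sum(edge_m[[e]] * graph$edge_e[[e]]), 1))
  S <- -sum(vapply(seq_len(ne), function(e) xlogx(as.vector(edge_m[[e]])), 1)) +
    sum(vapply(seq_len(n), function(i) (deg[i] - 1) * xlogx(node_m[[i]]), 1))
  F <- U - T * S

  structure(list(node_marginals = node_m, edge_marginals = edge_m,
                 free_energy = F, converged = converged, iterations = iter,
                 lmsg = list(fw = msg_fw, bw = msg_bw)),
            class = "cg_beliefs")
}

#' @export
print.cg_beliefs <- function(x, ...) {
  cat(sprintf("<cg_beliefs: F = %.6g, %sconverged in %d iterations>\n",
              x$free_energy, if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Side-chain forces from converged beliefs
#'
#' Differentiates the Bethe free energy holding the converged beliefs fixed
#' (exact at the Bethe stationary point; exact on trees): the coordinate
#' gradient is the expectation of per-state and per-pair energy gradients
#' under the node and edge marginals, and the parameter gradient is the
#' matching expectation of spline basis functions.  Bead-level gradients are
#' pulled back through the bead-placement Jacobians onto the backbone atoms;
#' gradients on O/H/CB sites are returned for the caller to pull back with
#' the frame Jacobians.
#'
#' @param graph a `cg_rotamer_graph` built with `want_grad = TRUE`.
#' @param beliefs a `cg_beliefs` from [run_bp()].
#' @param state,frame the backbone state and derived frame used to build the
#'   graph.
#' @param dalpha optional numeric vector (length of [flatten_params()]) to
#'   accumulate parameter derivatives into (requires the graph built with
#'   `want_param = TRUE`).
#' @param pset the parameter set (needed for alpha offsets when `dalpha` is
#'   given).
#' @return list with `grad` (backbone-atom gradient including bead pullback),
#'   `site_grads` (list O/H/CB) and `dalpha` (or `NULL`).
#' @export
sidechain_forces <- function(graph, beliefs, state, frame,
                             dalpha = NULL, pset = NULL) {
  n <- graph$n
  grad <- matrix(0, 3 * n, 3)
  gO <- matrix(0, n, 3); gH <- matrix(0, n, 3); gCB <- matrix(0, n, 3)
  m <- nrow(graph$sidx)
  g_bead_pos <- matrix(0, m, 3)
  g_bead_ori <- matrix(0, m, 3)
  want_alpha <- !is.null(dalpha)
  if (want_alpha && !graph$want_param)
    cg_error("cg_bp_error", "graph was built without parameter bases")
  off <- if (want_alpha) alpha_offsets(pset) else NULL

  add_site_grad <- function(kind, i, gv) {
    if (kind == "O") gO[i, ] <<- gO[i, ] + gv
    else if (kind == "H") gH[i, ] <<- gH[i, ] + gv
    else if (kind == "CB") gCB[i, ] <<- gCB[i, ] + gv
    else grad[atom_row(i, kind), ] <<- grad[atom_row(i, kind), ] + gv
  }

  # ---- node (bead-backbone) terms -----------------------------------------
  br <- graph$bb_rows
  if (!is.null(br) && nrow(br$tab)) {
    w <- vapply(seq_len(nrow(br$tab)), function(q) {
      r <- br$tab[q, 1]
      beliefs$node_marginals[[graph$sidx[r, 1]]][graph$sidx[r, 2]]
    }, 1)
    ev <- br$ev
    g_bead_pos_rows <- w * ev$gY1
    g_bead_ori_rows <- w * ev$gN1
    for (q in seq_len(nrow(br$tab))) {
      r <- br$tab[q, 1]
      g_bead_pos[r, ] <- g_bead_pos[r, ] + g_bead_pos_rows[q, ]
      g_bead_ori[r, ] <- g_bead_ori[r, ] + g_bead_ori_rows[q, ]
      j <- br$tab[q, 2]; site <- BB_SITES[br$tab[q, 3]]
      # gradient on the site position
      add_site_grad(site, j, w[q] * ev$gY2[q, ])
      # gradient through the site orientation (a normalized difference)
      ends <- switch(site, H = c("N", "H"), O = c("C", "O"),
                     N = c("CA", "N"), CA = c("CA", "CB"), C = c("C", "O"))
      ch <- unit_vec_chain(br$from_pt[q, ], br$to_pt[q, ], w[q] * ev$gN2[q, ])
      add_site_grad(ends[1], j, ch$ga)
      add_site_grad(ends[2], j, ch$gb)
    }
    if (want_alpha) {
      for (k in unique(br$pair_k)) {
        sel <- which(br$pair_k == k)
        o <- off$bb_start + (k - 1) * off$bb_len
        nb <- pset$config$bb_n
        dalpha[o + 1] <- dalpha[o + 1] + sum(w[sel] * ev$dkappa[sel])
        i0 <- o + 1
        dalpha[(i0 + 1):(i0 + nb[["radial"]])] <-
          dalpha[(i0 + 1):(i0 + nb[["radial"]])] +
          colSums(w[sel] * ev$b_radial[sel, , drop = FALSE])
        i0 <- i0 + nb[["radial"]]
        dalpha[(i0 + 1):(i0 + nb[["angular"]])] <-
          dalpha[(i0 + 1):(i0 + nb[["angular"]])] +
          colSums(w[sel] * ev$b_angular[sel, , drop = FALSE])
        i0 <- i0 + nb[["angular"]]
        dalpha[(i0 + 1):(i0 + nb[["ang1"]])] <-
          dalpha[(i0 + 1):(i0 + nb[["ang1"]])] +
          colSums(w[sel] * ev$b_ang1[sel, , drop = FALSE])
        i0 <- i0 + nb[["ang1"]]
        dalpha[(i0 + 1):(i0 + nb[["ang2"]])] <-
          dalpha[(i0 + 1):(i0 + nb[["ang2"]])] +
          colSums(w[sel] * ev$b_ang2[sel, , drop = FALSE])
      }
    }
  }

  # ---- edge (bead-bead) terms ---------------------------------------------
  ne <- if (is.null(graph$edges)) 0L else nrow(graph$edges)
  for (e in seq_len(ne)) {
    er <- graph$edge_rows[[e]]
    bm <- beliefs$edge_marginals[[e]]
    i <- graph$edges[e, 1]; j <- graph$edges[e, 2]
    ri <- graph$rows_of[[i]]; rj <- graph$rows_of[[j]]
    w <- as.vector(bm[cbind(match(er$grid$a, ri), match(er$grid$b, rj))])
    ev <- er$ev
    gp1 <- w * ev$gY1; go1 <- w * ev$gN1
    gp2 <- w * ev$gY2; go2 <- w * ev$gN2
    for (q in seq_along(w)) {
      a <- er$grid$a[q]; b <- er$grid$b[q]
      g_bead_pos[a, ] <- g_bead_pos[a, ] + gp1[q, ]
      g_bead_ori[a, ] <- g_bead_ori[a, ] + go1[q, ]
      g_bead_pos[b, ] <- g_bead_pos[b, ] + gp2[q, ]
      g_bead_ori[b, ] <- g_bead_ori[b, ] + go2[q, ]
    }
    if (want_alpha) {
      k <- ev$pair_index
      o <- off$sc_start + (k - 1) * off$sc_len
      nb <- pset$config$sc_n
      dalpha[o + 1] <- dalpha[o + 1] + sum(w * ev$dkappa)
      i0 <- o + 1
      dalpha[(i0 + 1):(i0 + nb[["radial"]])] <-
        dalpha[(i0 + 1):(i0 + nb[["radial"]])] + colSums(w * ev$b_radial)
      i0 <- i0 + nb[["radial"]]
      dalpha[(i0 + 1):(i0 + nb[["angular"]])] <-
        dalpha[(i0 + 1):(i0 + nb[["angular"]])] + colSums(w * ev$b_angular)
      i0 <- i0 + nb[["angular"]]
      dalpha[(i0 + 1):(i0 + nb[["ang1"]])] <-
        dalpha[(i0 + 1):(i0 + nb[["ang1"]])] + colSums(w * ev$b_ang1)
      i0 <- i0 + nb[["ang1"]]
      dalpha[(i0 + 1):(i0 + nb[["ang2"]])] <-
        dalpha[(i0 + 1):(i0 + nb[["ang2"]])] + colSums(w * ev$b_ang2)
    }
  }

  # ---- pull bead gradients back to the owning residue's backbone atoms ----
  for (r in seq_len(m)) {
    gp <- g_bead_pos[r, ]; go <- g_bead_ori[r, ]
    if (all(gp == 0) && all(go == 0)) next
    contrib <- gp[1] * graph$Jpos[r, 1, ] + gp[2] * graph$Jpos[r, 2, ] +
      gp[3] * graph$Jpos[r, 3, ] +
      go[1] * graph$Jori[r, 1, ] + go[2] * graph$Jori[r, 2, ] +
      go[3] * graph$Jori[r, 3, ]
    i <- graph$sidx[r, 1]
    grad[atom_row(i, "N"), ] <- grad[atom_row(i, "N"), ] + contrib[1:3]
    grad[atom_row(i, "CA"), ] <- grad[atom_row(i, "CA"), ] + contrib[4:6]
    grad[atom_row(i, "C"), ] <- grad[atom_row(i, "C"), ] + contrib[7:9]
  }

  list(grad = grad, site_grads = list(O = gO, H = gH, CB = gCB),
       dalpha = dalpha)
}

# offsets of the flattened-parameter blocks
alpha_offsets <- function(pset) {
  sc_len <- 1L + sum(pset$config$sc_n)
  bb_len <- 1L + sum(pset$config$bb_n)
  sc_start <- 0L
  bb_start <- 210L * sc_len
  env_start <- bb_start + 100L * bb_len
  bias_pos <- env_start + 20L * pset$config$env_n + 1L
  mag_pos <- bias_pos + 1L
  list(sc_start = sc_start, sc_len = sc_len,
       bb_start = bb_start, bb_len = bb_len,
       env_start = env_start, env_len = pset$config$env_n,
       bias_pos = bias_pos, mag_pos = mag_pos)
}
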