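# Independent reference implementations used to cross-check the package:
# a quaternion-based RMSD oracle, a finite-difference gradient helper, and
# brute-force enumeration of small factor graphs.

# Horn's quaternion method for optimal superposition RMSD: an algorithm
# independent of the SVD-based Kabsch implementation in the package.
quaternion_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  M <- t(B0) %*% A0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# central finite-difference gradient of a scalar function of a vector
fd_gradient <- function(f, x, h = 1e-6, idx = seq_along(x)) {
  vapply(idx, function(k) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# random factor graph in the minimal shape accepted by run_bp():
# a labeled tree on n nodes (Pruefer-free: attach node k to a random earlier
# node) or a single cycle.
random_graph <- function(n_nodes, max_states, seed, topology = c("tree",
                                                                 "cycle"),
                         scale = 1) {
  topology <- match.arg(topology)
  set.seed(seed)
  nstates <- sample.int(max_states, n_nodes, replace = TRUE)
  node_e <- lapply(nstates, function(k) scale * rnorm(k))
  if (topology == "tree") {
    edges <- if (n_nodes >= 2)
      cbind(vapply(2:n_nodes, function(k) sample.int(k - 1L, 1), 1L),
            2:n_nodes)
    else NULL
  } else {
    stopifnot(n_nodes >= 3)
    edges <- cbind(1:n_nodes, c(2:n_nodes, 1L))
    edges <- t(apply(edges, 1, sort))
  }
  edge_e <- if (is.null(edges)) list() else
    lapply(seq_len(nrow(edges)), function(e)
      matrix(scale * rnorm(nstates[edges[e, 1]] * nstates[edges[e, 2]]),
             nstates[edges[e, 1]], nstates[edges[e, 2]]))
  list(n = n_nodes, nstates = nstates, node_e = node_e, edges = edges,
       edge_e = edge_e)
}

# exact free energy and marginals of a small factor graph by enumeration
enumerate_graph <- function(graph, temperature = 1) {
  combs <- expand.grid(lapply(graph$nstates, seq_len))
  E <- apply(combs, 1, function(s) {
    e <- sum(mapply(function(i, si) graph$node_e[[i]][si],
                    seq_along(s), s))
    if (!is.null(graph$edges))
      for (q in seq_len(nrow(graph$edges))) {
        i <- graph$edges[q, 1]; j <- graph$edges[q, 2]
        e <- e + graph$edge_e[[q]][s[i], s[j]]
      }
    e
  })
  w <- exp(-(E - min(E)) / temperature)
  Z <- sum(w)
  p <- w / Z
  marg <- lapply(seq_len(graph$n), function(i)
    vapply(seq_len(graph$nstates[i]), function(s)
      sum(p[combs[, i] == s]), 1))
  list(free_energy = -temperature * (log(Z) - min(E) / temperature),
       marginals = marg)
}

# small mixed-sequence backbone used by several gradient tests
mixed_fixture <- function(nres = 8, seed = 4) {
  make_backbone("coil", nres = nres,
                sequence = c("M", "K", "V", "L", "F", "S", "T", "W",
                             "G", "P")[seq_len(nres)],
                seed = seed)
}
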