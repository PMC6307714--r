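test_that("total energy is invariant under rigid motions", {
  st <- mixed_fixture(7)
  pset <- make_toy_parameters(seed = 3, scale = 0.2)
  e0 <- total_energy(st, pset)
  # translation
  st2 <- st; st2$x <- st$x + matrix(c(3, -2, 5), nrow(st$x), 3, byrow = TRUE)
  e1 <- total_energy(st2, pset)
  expect_equal(e1$energy, e0$energy, tolerance = 1e-9)
  # rotation
  R <- cgfold:::rotation_about_axis(c(1, 2, 0.5), 1.1)
  st3 <- st; st3$x <- st$x %*% t(R)
  e2 <- total_energy(st3, pset)
  expect_equal(e2$energy, e0$energy, tolerance = 1e-8)
  # translation invariance implies the gradient sums to zero
  expect_equal(colSums(e0$grad), c(0, 0, 0), tolerance = 1e-8)
  expect_equal(e0$energy, sum(e0$terms), tolerance = 1e-12)
})

test_that("full coordinate gradient matches finite differences", {
  st <- mixed_fixture(7)
  pset <- make_toy_parameters(seed = 3, scale = 0.2)
  te <- total_energy(st, pset)
  f <- function(xflat) {
    s <- st; s$x <- matrix(xflat, ncol = 3)
    total_energy(s, pset)$energy
  }
  set.seed(10)
  idx <- sample(length(st$x), 10)
  fd <- fd_gradient(f, as.vector(st$x), idx = idx)
  an <- as.vector(te$grad)[idx]
  expect_equal(an, fd, tolerance = 1e-5)
})

test_that("parameter gradient matches finite differences across all blocks", {
  st <- mixed_fixture(6)
  pset <- make_toy_parameters(seed = 3, scale = 0.2)
  te <- total_energy(st, pset, want_dalpha = TRUE)
  alpha <- flatten_params(pset)
  off <- cgfold:::alpha_offsets(pset)
  # pick indices covering every block: sc kappa/curves, bb, env, scalars
  idx <- c(off$sc_start + 64 * 0 + 1,           # a kappa
           35, 80, 1200,                        # sc curve coefficients
           off$bb_start + 3, off$bb_start + 200,
           off$env_start + 5, off$env_start + 195,
           off$bias_pos, off$mag_pos)
  idx <- unique(pmin(pmax(idx, 1), length(alpha)))
  f <- function(a) total_energy(st, unflatten_params(pset, a))$energy
  fd <- fd_gradient(f, alpha, idx = idx)
  expect_equal(te$dalpha[idx], fd, tolerance = 1e-5)
})

test_that("switching sidechain off removes exactly that term", {
  st <- mixed_fixture(6)
  pset <- make_toy_parameters(seed = 4, scale = 0.15)
  e_on <- total_energy(st, pset, sidechain = TRUE)
  e_off <- total_energy(st, pset, sidechain = FALSE)
  expect_equal(e_on$energy - e_on$terms[["sidechain"]], e_off$energy,
               tolerance = 1e-10)
  expect_identical(e_off$terms[["sidechain"]], 0)
})

test_that("sidechain free energy rises with temperature (prior-weighted)", {
  st <- mixed_fixture(8)
  pset <- make_toy_parameters(seed = 5, scale = 0.2)
  f1 <- total_energy(st, pset, temperature = 0.5)$terms[["sidechain"]]
  f2 <- total_energy(st, pset, temperature = 2)$terms[["sidechain"]]
  # With normalized rotamer prior weights folded in as -T log w, the
  # envelope derivative is dF/dT = sum_i E_b[log(1/w_i)] - S >= 0 (the
  # joint entropy never exceeds the sum of node entropies, and each node
  # term is a KL divergence against the prior), so F is non-decreasing
  # in temperature.
  expect_gt(f2, f1)
})

test_that("force provider applies restraints and reports flat gradients", {
  st <- mixed_fixture(6)
  pset <- make_toy_parameters(seed = 6, scale = 0.1)
  ref <- make_backbone("helix", nres = 6, sequence = st$seq)
  spec <- restraint_spec(ref, radius = 0.5, k = 25)
  prov <- make_force_provider(st, pset, restraint = spec)
  out <- prov(as.vector(st$x))
  expect_length(out$grad, length(st$x))
  base <- total_energy(st, pset)$energy
  re <- eval_restraint(st, spec)
  expect_equal(out$energy, base + re$energy, tolerance = 1e-9)
})
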