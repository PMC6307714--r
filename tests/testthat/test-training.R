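test_that("flat-bottom restraint is zero inside and smooth outside", {
  ref <- make_backbone("helix", nres = 6)
  spec <- restraint_spec(ref, radius = 1.0, k = 50)
  # inside the flat bottom: tiny perturbation
  st <- ref
  set.seed(1)
  st$x <- st$x + matrix(rnorm(length(st$x), sd = 0.02), nrow(st$x), 3)
  re <- eval_restraint(st, spec)
  expect_lt(re$rmsd, 1)
  expect_identical(re$energy, 0)
  expect_identical(re$grad, matrix(0, nrow(st$x), 3))
  # outside: energy is 0.5 k (rmsd - r0)^2 and the gradient matches FD
  st2 <- ref
  st2$x <- st2$x + matrix(rnorm(length(st2$x), sd = 1.5), nrow(st2$x), 3)
  re2 <- eval_restraint(st2, spec)
  expect_gt(re2$rmsd, 1)
  expect_equal(re2$energy, 0.5 * 50 * (re2$rmsd - 1)^2, tolerance = 1e-10)
  f <- function(xflat) {
    s <- st2; s$x <- matrix(xflat, ncol = 3)
    eval_restraint(s, spec)$energy
  }
  idx <- sample(length(st2$x), 8)
  fd <- fd_gradient(f, as.vector(st2$x), idx = idx)
  expect_equal(as.vector(re2$grad)[idx], fd, tolerance = 1e-5)
  # rigid motions leave the restraint at zero
  R <- cgfold:::rotation_about_axis(c(0, 1, 1), 0.7)
  st3 <- ref; st3$x <- ref$x %*% t(R) + 2
  expect_identical(eval_restraint(st3, spec)$energy, 0)
})

test_that("cd_update has the correct sign and validates shapes", {
  # harmonic toy: V_k(x) = 0.5 k x^2, dV/dk = 0.5 x^2.
  # data at k* = 2, model at k = 0.5: free fluctuations exceed the data,
  # so the update must increase k.
  set.seed(2)
  k_true <- 2; k0 <- 0.5; T <- 1
  g_data <- mean(0.5 * rnorm(4000, sd = sqrt(T / k_true))^2)
  g_free <- mean(0.5 * rnorm(4000, sd = sqrt(T / k0))^2)
  k1 <- cd_update(k0, g_free, g_data, epsilon = 0.5)
  expect_gt(k1, k0)
  expect_error(cd_update(c(1, 2), matrix(1, 1, 3), matrix(1, 1, 2), 0.1),
               class = "cg_parameter_mismatch_error")
})

test_that("contrastive divergence recovers a known stiffness", {
  # exact Gaussian samplers stand in for the MD ensembles; the fixed point
  # of the update is <0.5 x^2>_free = <0.5 x^2>_data, i.e. k = k*
  set.seed(3)
  k_true <- 2; T <- 1
  k <- 0.5
  eps <- 0.4
  n_up <- 0
  for (it in 1:200) {
    n_up <- it
    g_data <- mean(0.5 * rnorm(400, sd = sqrt(T / k_true))^2)
    g_free <- mean(0.5 * rnorm(400, sd = sqrt(T / k))^2)
    k <- cd_update(k, g_free, g_data, eps)
    if (abs(k - k_true) / k_true < 0.05) break
  }
  expect_lte(n_up, 200)
  expect_lt(abs(k - k_true) / k_true, 0.10)
})

test_that("minibatch partition is fixed, exhaustive and sized correctly", {
  b1 <- cgfold:::make_minibatches(456, 12, seed = 7)
  b2 <- cgfold:::make_minibatches(456, 12, seed = 7)
  expect_identical(b1, b2)
  expect_length(b1, 38)
  expect_identical(sort(unlist(b1)), 1:456)
  expect_true(all(lengths(b1) == 12))
  # non-divisible case
  b3 <- cgfold:::make_minibatches(10, 4, seed = 1)
  expect_length(b3, 3)
  expect_identical(sort(unlist(b3)), 1:10)
})

test_that("sampled ensembles produce derivative matrices and restrained RMSD", {
  st <- make_backbone("helix", nres = 5)
  pset <- make_toy_parameters(seed = 4, scale = 0.1)
  spec <- restraint_spec(st, radius = 1, k = 50)
  ens <- sample_ensemble(st, pset, steps = 40,
                         ladder = make_ladder(1, 1, nres = 5),
                         restraint = spec, record_every = 10,
                         pivot_every = 20, swap_every = 0,
                         sidechain = FALSE, seed = 21)
  expect_identical(ncol(ens$dalpha), length(flatten_params(pset)))
  expect_gte(nrow(ens$dalpha), 2)
  expect_true(is.finite(ens$mean_rmsd))
  expect_lt(ens$mean_rmsd, 2)
  # seeded runs are reproducible
  ens2 <- sample_ensemble(st, pset, steps = 40,
                          ladder = make_ladder(1, 1, nres = 5),
                          restraint = spec, record_every = 10,
                          pivot_every = 20, swap_every = 0,
                          sidechain = FALSE, seed = 21)
  expect_identical(ens$dalpha_mean, ens2$dalpha_mean)
})

test_that("train_cd runs, decays the step size and returns a cd_fit", {
  natives <- list(make_backbone("helix", nres = 5),
                  make_backbone("strand", nres = 5, seed = 2))
  pset <- new_parameter_set()
  fit <- train_cd(natives, pset, n_updates = 5, minibatch_size = 2,
                  epsilon = 0.02, decay_passes = 2, steps = 20,
                  record_every = 10, pivot_every = 0, swap_every = 0,
                  sidechain = FALSE, seed = 11)
  expect_s3_class(fit, "cd_fit")
  expect_identical(nrow(fit$history), 5L)
  # minibatch = all systems, so each update is one pass; after 2 and 4
  # passes the step size is divided by 4
  expect_equal(fit$history$epsilon, 0.02 * c(1, 1, 0.25, 0.25, 0.0625),
               tolerance = 1e-12)
  expect_length(coef(fit), length(flatten_params(pset)))
  expect_output(print(fit), "contrastive-divergence")
  # parameters actually moved
  expect_gt(max(abs(coef(fit) - flatten_params(pset))), 0)
})
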