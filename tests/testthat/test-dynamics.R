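# Analytic force providers used to test the integrator in isolation.
harmonic_provider <- function(k) function(x)
  list(energy = 0.5 * k * sum(x^2), grad = k * x)

test_that("BAOAB with zero friction conserves energy (velocity Verlet)", {
  prov <- harmonic_provider(1)
  cfg <- thermostat_config(temperature = 0, gamma = 0, dt = 0.01)
  dyn <- cgfold:::init_dyn(c(1, 0), prov, p = c(0, 1))
  e0 <- dyn$energy + 0.5 * sum(dyn$p^2)
  for (s in 1:2000) dyn <- langevin_step(dyn, prov, cfg)
  e1 <- dyn$energy + 0.5 * sum(dyn$p^2)
  expect_equal(e1, e0, tolerance = 1e-4)
})

test_that("BAOAB thermostat equipartitions a harmonic oscillator", {
  set.seed(42)
  k <- 2; T <- 0.8
  prov <- harmonic_provider(k)
  cfg <- thermostat_config(temperature = T, gamma = 1, dt = 0.05)
  dyn <- cgfold:::init_dyn(c(0.5, -0.5, 0.2), prov)
  nst <- 30000L
  xs <- ps <- matrix(0, nst, 3)
  for (s in seq_len(nst)) {
    dyn <- langevin_step(dyn, prov, cfg)
    xs[s, ] <- dyn$x; ps[s, ] <- dyn$p
  }
  keep <- 2001:nst
  # batch means for an honest standard error under autocorrelation
  bmean <- function(v, nb = 20) {
    m <- matrix(v[seq_len(nb * (length(v) %/% nb))], ncol = nb)
    colMeans(m)
  }
  for (d in 1:3) {
    bx <- bmean(k * xs[keep, d]^2)
    bp <- bmean(ps[keep, d]^2)
    se_x <- sd(bx) / sqrt(length(bx))
    se_p <- sd(bp) / sqrt(length(bp))
    expect_lt(abs(mean(bx) - T), 4 * se_x + 0.01)
    expect_lt(abs(mean(bp) - T), 4 * se_p + 0.01)
  }
})

test_that("non-finite forces raise a classed integration error", {
  bad <- function(x) list(energy = NaN, grad = rep(NaN, length(x)))
  cfg <- thermostat_config()
  dyn <- list(x = c(0, 0), p = c(0, 0), f = c(0, NaN), energy = 0)
  expect_error(langevin_step(dyn, bad, cfg),
               class = "cg_integration_error")
})

test_that("pivot moves preserve covalent geometry exactly", {
  set.seed(7)
  st <- make_backbone("coil", nres = 9, seed = 3)
  pset <- make_toy_parameters(seed = 1, scale = 0.1)
  eprov <- function(s) total_energy(s, pset, sidechain = FALSE)$energy
  st2 <- st
  for (q in 1:10) {
    pm <- pivot_move(st2, eprov, temperature = 2)
    st2 <- pm$state
  }
  expect_false(isTRUE(all.equal(st$x, st2$x)))  # something moved
  expect_silent(validate_backbone(st2))
  # bond angles are preserved too
  for (i in 2:8) {
    a0 <- cgfold:::angle_grad(st$x[cgfold:::atom_row(i, "N"), ],
                              st$x[cgfold:::atom_row(i, "CA"), ],
                              st$x[cgfold:::atom_row(i, "C"), ])$angle
    a1 <- cgfold:::angle_grad(st2$x[cgfold:::atom_row(i, "N"), ],
                              st2$x[cgfold:::atom_row(i, "CA"), ],
                              st2$x[cgfold:::atom_row(i, "C"), ])$angle
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("pivot at zero temperature only accepts downhill moves", {
  set.seed(8)
  st <- make_backbone("helix", nres = 6)
  eprov <- function(s) sum((ca_coords(s))^2)  # arbitrary smooth energy
  e0 <- eprov(st)
  for (q in 1:20) {
    pm <- pivot_move(st, eprov, temperature = 0, energy = e0)
    if (pm$accepted) expect_lte(pm$energy, e0)
    st <- pm$state; e0 <- pm$energy
  }
})

test_that("ladder spacing scales inversely with chain length", {
  l100 <- make_ladder(4, t_min = 1, base_interval = 0.1, nres = 100)
  l200 <- make_ladder(4, t_min = 1, base_interval = 0.1, nres = 200)
  expect_equal(diff(l100$temperatures), rep(0.1, 3), tolerance = 1e-12)
  expect_equal(diff(l200$temperatures), rep(0.05, 3), tolerance = 1e-12)
  expect_equal(l100$temperatures[1], 1)
  expect_true(all(diff(l100$temperatures) > 0))
})

test_that("replica exchange swaps correctly and alternates parity", {
  set.seed(9)
  cfgs <- as.list(1:4)
  temps <- c(1, 1.2, 1.4, 1.6)
  # equal energies: every attempt accepted (delta = 0)
  rx <- replica_exchange_step(cfgs, rep(5, 4), temps, parity = "even")
  expect_identical(unlist(rx$configs), c(2L, 1L, 4L, 3L))
  expect_true(all(rx$accepted))
  rx2 <- replica_exchange_step(cfgs, rep(5, 4), temps, parity = "odd")
  expect_identical(unlist(rx2$configs), c(1L, 3L, 2L, 4L))
  # a hugely unfavorable swap is rejected: it would move the high-energy
  # configuration to the cold replica
  rx3 <- replica_exchange_step(as.list(1:2), c(0, 1000), c(1, 1.1), "even")
  expect_false(any(rx3$accepted))
  expect_identical(unlist(rx3$configs), 1:2)
  # two replicas with odd parity: no valid pair, nothing happens
  rx4 <- replica_exchange_step(as.list(1:2), c(0, 0), c(1, 1.1), "odd")
  expect_length(rx4$accepted, 0)
})

test_that("replica-exchange swap acceptance follows the Metropolis rule", {
  # E_cold > E_hot makes the swap favorable: always accepted
  rx <- replica_exchange_step(as.list(1:2), c(10, 0), c(1, 2), "even")
  expect_true(all(rx$accepted))
  expect_identical(rx$energies, c(0, 10))
})

test_that("the hybrid sampler runs, records and reports rates", {
  set.seed(11)
  st <- make_backbone("helix", nres = 6)
  pset <- make_toy_parameters(seed = 2, scale = 0.1)
  sim <- simulate_replex(st, pset, steps = 60,
                         ladder = make_ladder(2, 1, nres = 6),
                         record_every = 20, pivot_every = 30,
                         swap_every = 20, sidechain = FALSE)
  expect_length(sim$frames, 3)
  expect_length(sim$energies, 3)
  expect_true(all(vapply(sim$frames, inherits, TRUE, "cg_backbone")))
  expect_true(sim$pivot_rate >= 0 && sim$pivot_rate <= 1)
  expect_true(is.na(sim$swap_rate) || (sim$swap_rate >= 0 &&
                                       sim$swap_rate <= 1))
  expect_length(sim$final_states, 2)
})
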