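test_that("belief propagation is exact on small trees", {
  for (s in 1:25) {
    g <- random_graph(n_nodes = sample(2:6, 1), max_states = 6,
                      seed = 1000 + s, topology = "tree")
    ex <- enumerate_graph(g, temperature = 1)
    bp <- run_bp(g, temperature = 1)
    expect_true(bp$converged)
    expect_equal(bp$free_energy, ex$free_energy, tolerance = 1e-10)
    for (i in seq_len(g$n))
      expect_equal(bp$node_marginals[[i]], ex$marginals[[i]],
                   tolerance = 1e-10)
  }
})

test_that("belief propagation handles edgeless and single-node graphs", {
  g <- random_graph(n_nodes = 1, max_states = 5, seed = 3,
                    topology = "tree")
  bp <- run_bp(g, temperature = 0.7)
  ex <- enumerate_graph(g, temperature = 0.7)
  expect_equal(bp$free_energy, ex$free_energy, tolerance = 1e-12)
  expect_equal(bp$node_marginals[[1]], ex$marginals[[1]], tolerance = 1e-12)
  expect_true(bp$converged)
})

test_that("temperature scales the free energy sensibly", {
  g <- random_graph(n_nodes = 5, max_states = 4, seed = 17,
                    topology = "tree")
  for (T in c(0.5, 1, 2)) {
    ex <- enumerate_graph(g, temperature = T)
    bp <- run_bp(g, temperature = T)
    expect_equal(bp$free_energy, ex$free_energy, tolerance = 1e-9)
  }
  expect_error(run_bp(g, temperature = 0), class = "cg_bp_error")
})

test_that("edge marginals are consistent with node marginals on trees", {
  g <- random_graph(n_nodes = 6, max_states = 5, seed = 23,
                    topology = "tree")
  bp <- run_bp(g, 1)
  for (e in seq_len(nrow(g$edges))) {
    bm <- bp$edge_marginals[[e]]
    expect_equal(sum(bm), 1, tolerance = 1e-10)
    expect_equal(rowSums(bm), bp$node_marginals[[g$edges[e, 1]]],
                 tolerance = 1e-8)
    expect_equal(colSums(bm), bp$node_marginals[[g$edges[e, 2]]],
                 tolerance = 1e-8)
  }
})

test_that("loopy graphs with weak coupling stay near the exact answer", {
  for (s in 1:10) {
    g <- random_graph(n_nodes = 4, max_states = 3, seed = 2000 + s,
                      topology = "cycle", scale = 0.15)
    ex <- enumerate_graph(g, 1)
    bp <- run_bp(g, 1)
    expect_true(bp$converged)
    expect_lt(abs(bp$free_energy - ex$free_energy), 1e-3)
    for (i in seq_len(g$n))
      expect_lt(max(abs(bp$node_marginals[[i]] - ex$marginals[[i]])), 1e-3)
  }
})

test_that("warm starts converge to the same answer and bad ones are ignored", {
  g <- random_graph(n_nodes = 5, max_states = 4, seed = 31,
                    topology = "cycle", scale = 0.3)
  a <- run_bp(g, 1)
  b <- run_bp(g, 1, init = a$lmsg)
  expect_equal(b$free_energy, a$free_energy, tolerance = 1e-9)
  expect_lte(b$iterations, a$iterations)
  # mismatched warm start (wrong edge count) must not crash
  g2 <- random_graph(n_nodes = 6, max_states = 4, seed = 32,
                     topology = "tree")
  c2 <- run_bp(g2, 1, init = a$lmsg)
  ex <- enumerate_graph(g2, 1)
  expect_equal(c2$free_energy, ex$free_energy, tolerance = 1e-9)
})

test_that("side-chain Bethe free energy matches enumeration on a real graph", {
  st <- mixed_fixture(6)
  pset <- make_toy_parameters(seed = 2, scale = 0.2)
  fr <- place_virtual_sites(st, jacobian = TRUE,
                            burial_params = pset$burial)
  g <- build_rotamer_graph(st, fr, pset, default_rotamer_library(),
                           temperature = 1)
  bp <- run_bp(g, 1)
  ex <- enumerate_graph(g, 1)
  expect_true(bp$converged)
  # the rotamer graph is loopy, so Bethe is an approximation; it must be
  # close but need not be exact
  expect_lt(abs(bp$free_energy - ex$free_energy), 0.05)
})
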