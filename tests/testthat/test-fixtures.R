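test_that("backbone fixtures are reproducible and validated", {
  a <- make_backbone("coil", nres = 9, seed = 13)
  b <- make_backbone("coil", nres = 9, seed = 13)
  expect_identical(a$x, b$x)
  c2 <- make_backbone("coil", nres = 9, seed = 14)
  expect_false(isTRUE(all.equal(a$x, c2$x)))
  expect_silent(validate_backbone(a))
  # dipeptide forces three residues
  expect_identical(make_backbone("dipeptide")$nres, 3L)
  # noise perturbs coordinates but is seeded
  n1 <- make_backbone("helix", nres = 5, seed = 3, noise = 0.05)
  n2 <- make_backbone("helix", nres = 5, seed = 3, noise = 0.05)
  expect_identical(n1$x, n2$x)
  expect_false(isTRUE(all.equal(n1$x, make_backbone("helix", nres = 5)$x)))
})

test_that("coil fixtures sample plausible Ramachandran angles", {
  st <- make_backbone("coil", nres = 40, seed = 5)
  dh <- backbone_dihedrals(st)
  phi <- dh[2:40, "phi"]
  expect_true(all(phi >= -pi & phi <= pi))
  # most residues should fall in the broad favorable phi < 0 half
  expect_gt(mean(phi < 0), 0.6)
})

test_that("toy parameter sets have the advertised structure", {
  pset <- make_toy_parameters(seed = 1, scale = 0.1)
  ct <- count_parameters(pset)
  expect_identical(ct$sc_pair_types, 210L)
  expect_identical(ct$sc_pair_params, 13020L)
  expect_identical(ct$bb_pair_params, 5400L)
  expect_identical(ct$env_params, 200L)
  expect_identical(ct$scalars, 2L)
  expect_identical(ct$kappas, 310L)
  expect_identical(ct$total_trainable,
                   310L + 13020L + 5400L + 200L + 2L)
  # scale 0 gives the all-zero trainable set
  p0 <- make_toy_parameters(seed = 1, scale = 0)
  a0 <- flatten_params(p0)
  expect_true(all(a0[a0 != 1] == 0))   # kappas are 1, everything else 0
})

test_that("flatten/unflatten are exact inverses", {
  pset <- make_toy_parameters(seed = 2, scale = 0.3)
  alpha <- flatten_params(pset)
  p2 <- unflatten_params(new_parameter_set(), alpha)
  expect_identical(flatten_params(p2), alpha)
  expect_error(unflatten_params(pset, alpha[-1]),
               class = "cg_parameter_mismatch_error")
})

test_that("the two-basin toy matches closed-form Gaussian limits", {
  toy <- make_two_basin_toy(barrier = 2, tilt = 0)
  ref <- toy$reference(1)
  expect_equal(ref$p_right, 0.5, tolerance = 1e-9)
  expect_gt(ref$var_E, 0)
  # force is minus the analytic derivative
  xs <- seq(-2, 2, length.out = 21)
  h <- 1e-6
  fd <- -(toy$energy(xs + h) - toy$energy(xs - h)) / (2 * h)
  expect_equal(toy$force(xs), fd, tolerance = 1e-6)
  # a tilt moves occupancy toward the lower well
  ref2 <- make_two_basin_toy(barrier = 2, tilt = 0.5)$reference(0.5)
  expect_lt(ref2$p_right, 0.5)
  # deep-well limit: energy moments approach two independent Gaussians,
  # <E> ~ T/2 per quadratic mode
  refd <- make_two_basin_toy(barrier = 50)$reference(0.2)
  expect_equal(refd$mean_E, 0.1, tolerance = 0.02)
})

test_that("parameter-set schema violations raise classed errors", {
  expect_error(new_parameter_set(sc = vector("list", 3)),
               class = "cg_schema_error")
  err <- tryCatch(new_parameter_set(env = vector("list", 7)),
                  error = function(e) e)
  expect_s3_class(err, "cg_schema_error")
  expect_identical(err$block, "env")
})
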