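test_that("pair potential gradients match finite differences", {
  pset <- make_toy_parameters(seed = 5, scale = 0.3)
  pp <- pset$sc_pairs[[17]]
  y1 <- c(0.3, -0.2, 0.1); n1 <- c(1, 0, 0)
  y2 <- c(3.1, 1.0, -0.4); n2 <- c(0, 0.6, 0.8)
  ev <- eval_pair(pp, y1, n1, y2, n2)
  pack <- c(y1, n1, y2, n2)
  f <- function(v) eval_pair(pp, v[1:3], v[4:6], v[7:9], v[10:12])$energy
  fd <- fd_gradient(f, pack)
  an <- c(ev$gY1, ev$gN1, ev$gY2, ev$gN2)
  expect_equal(an, unname(fd), tolerance = 1e-6)
})

test_that("pair energy is linear in coefficients with the reported basis", {
  pset <- make_toy_parameters(seed = 6, scale = 0.2)
  k <- 44L
  pp <- pset$sc_pairs[[k]]
  y1 <- c(0, 0, 0); n1 <- c(0, 1, 0)
  y2 <- c(4.2, 0.5, 0.3); n2 <- c(1, 0, 0)
  ev <- cgfold:::pair_eval_batch(pp, rbind(y1), rbind(n1), rbind(y2),
                                 rbind(n2), want_param = TRUE)
  # dE/dkappa * kappa equals the energy (energy = kappa * shape)
  expect_equal(ev$dkappa * pp$kappa, ev$energy, tolerance = 1e-10)
  # perturbing one radial coefficient changes E by basis value
  d <- 1e-3
  pp2 <- pp; pp2$radial$coef[6] <- pp2$radial$coef[6] + d
  ev2 <- cgfold:::pair_eval_batch(pp2, rbind(y1), rbind(n1), rbind(y2),
                                  rbind(n2), want_param = FALSE)
  expect_equal((ev2$energy - ev$energy) / d, ev$b_radial[1, 6],
               tolerance = 1e-8)
})

test_that("unordered side-chain pairs are evaluated symmetrically", {
  pset <- make_toy_parameters(seed = 7, scale = 0.3)
  y1 <- matrix(c(0, 0, 0), 1); n1 <- matrix(c(1, 0, 0), 1)
  y2 <- matrix(c(3.5, 1, 0), 1); n2 <- matrix(c(0, 1, 0), 1)
  e_ab <- cgfold:::sc_pair_batch(pset, "K", "F", y1, n1, y2, n2,
                                 FALSE)$energy
  e_ba <- cgfold:::sc_pair_batch(pset, "F", "K", y2, n2, y1, n1,
                                 FALSE)$energy
  expect_equal(e_ab, e_ba, tolerance = 1e-12)
  # like-type pairs are invariant under swapping the two beads
  e_aa <- cgfold:::sc_pair_batch(pset, "W", "W", y1, n1, y2, n2,
                                 FALSE)$energy
  e_aa2 <- cgfold:::sc_pair_batch(pset, "W", "W", y2, n2, y1, n1,
                                  FALSE)$energy
  expect_equal(e_aa, e_aa2, tolerance = 1e-12)
})

test_that("pair indices enumerate 210 and 100 types bijectively", {
  ks <- integer(0)
  for (i in seq_along(AA_CODES)) for (j in i:length(AA_CODES))
    ks <- c(ks, sc_pair_index(AA_CODES[i], AA_CODES[j])$index)
  expect_identical(sort(ks), 1:210)
  expect_identical(sc_pair_index("W", "A")$index,
                   sc_pair_index("A", "W")$index)
  expect_true(sc_pair_index("W", "A")$swapped)
  bs <- integer(0)
  for (s in cgfold:::BB_SITES) for (a in AA_CODES)
    bs <- c(bs, bb_pair_index(s, a))
  expect_identical(sort(bs), 1:100)
})

test_that("pair evaluation rejects coincident points", {
  pset <- make_toy_parameters(seed = 5, scale = 0.3)
  expect_error(eval_pair(pset$sc_pairs[[1]], c(1, 1, 1), c(1, 0, 0),
                         c(1, 1, 1), c(0, 1, 0)),
               class = "cg_degenerate_geometry_error")
})

test_that("Ramachandran term: derivatives, contexts and sheet bias", {
  pset <- make_toy_parameters(seed = 8, scale = 0.1)
  pset$sheet_bias <- 0.7
  ev <- eval_rama(pset, 0.4, -1.1)
  h <- 1e-6
  expect_equal((eval_rama(pset, 0.4 + h, -1.1)$value -
                eval_rama(pset, 0.4 - h, -1.1)$value) / (2 * h),
               ev$dphi, tolerance = 1e-5)
  expect_equal((eval_rama(pset, 0.4, -1.1 + h)$value -
                eval_rama(pset, 0.4, -1.1 - h)$value) / (2 * h),
               ev$dpsi, tolerance = 1e-5)
  # dbias is the bump value: linear in the bias
  p2 <- pset; p2$sheet_bias <- pset$sheet_bias + 1
  expect_equal(eval_rama(p2, 0.4, -1.1)$value - ev$value, ev$dbias,
               tolerance = 1e-12)
  # bump peaks at the canonical beta region
  b0 <- eval_rama(pset, -120 * pi / 180, 130 * pi / 180)$dbias
  expect_gt(b0, eval_rama(pset, -60 * pi / 180, -45 * pi / 180)$dbias)
  expect_equal(b0, 1, tolerance = 1e-12)
  # context selection
  sq <- c("A", "G", "A", "P", "A")
  expect_identical(cgfold:::rama_context(sq, 2), "gly")
  expect_identical(cgfold:::rama_context(sq, 3), "prepro")
  expect_identical(cgfold:::rama_context(sq, 4), "general")
  # periodicity
  expect_equal(eval_rama(pset, 0.4 + 2 * pi, -1.1)$value, ev$value,
               tolerance = 1e-10)
})

test_that("glycine prefers positive phi relative to other residues", {
  pset <- new_parameter_set()
  gg <- pset$rama$contexts$gly
  ge <- pset$rama$contexts$general
  phi <- 60 * pi / 180; psi <- 30 * pi / 180
  d_gly <- cgfold:::rama_interp(gg, phi, psi)$value
  d_gen <- cgfold:::rama_interp(ge, phi, psi)$value
  expect_lt(d_gly, d_gen)
})

test_that("helix hydrogen bonds score on the favorable plateau", {
  st <- make_backbone("helix", nres = 12)
  pset <- new_parameter_set()
  fr <- place_virtual_sites(st, jacobian = FALSE)
  hb <- eval_hbond(pset, st, fr)
  # the i -> i-4 alpha-helical register must be clearly favorable
  reg <- hb$scores[hb$scores$donor - hb$scores$acceptor == 4, ]
  expect_identical(nrow(reg), 8L)
  expect_true(all(reg$score > 0.5))
  # an extended strand has no internal hydrogen bonds
  ss <- make_backbone("strand", nres = 12)
  expect_identical(hbond_count(ss), 0L)
})

test_that("hydrogen-bond energy scales linearly with its magnitude", {
  st <- make_backbone("helix", nres = 8)
  fr <- place_virtual_sites(st, jacobian = FALSE)
  p1 <- new_parameter_set(hbond_magnitude = 1)
  p2 <- new_parameter_set(hbond_magnitude = 2.5)
  e1 <- eval_hbond(p1, st, fr)
  e2 <- eval_hbond(p2, st, fr)
  expect_equal(e2$energy, 2.5 * e1$energy, tolerance = 1e-12)
  expect_equal(e1$dmagnitude, e1$energy / 1, tolerance = 1e-12)
  expect_lt(e1$energy, 0)
})

test_that("steric term is a strictly decreasing compact repulsion", {
  sp <- cgfold:::STERIC_DEFAULTS
  r <- seq(0.4, sp$r_cut, length.out = 50)
  v <- sp$eps * (1 - r / sp$r_cut)^2
  expect_true(all(diff(v) < 0))
  expect_equal(v[50], 0, tolerance = 1e-12)
  # well-separated ideal helix has zero steric energy
  st <- make_backbone("helix", nres = 8)
  fr <- place_virtual_sites(st, jacobian = FALSE)
  ev <- eval_steric(st, fr, sp)
  expect_gte(ev$energy, 0)
  # compressing two residues onto each other must raise it
  st2 <- st
  st2$x[cgfold:::atom_row(5, "CA"), ] <- st2$x[cgfold:::atom_row(1, "CA"), ] + 0.5
  fr2 <- place_virtual_sites(st2, jacobian = FALSE)
  expect_gt(eval_steric(st2, fr2, sp)$energy, ev$energy)
})

test_that("environment energy matches its basis representation", {
  pset <- make_toy_parameters(seed = 9, scale = 0.4)
  st <- mixed_fixture(8)
  fr <- place_virtual_sites(st, jacobian = FALSE,
                            burial_params = pset$burial)
  ev <- eval_env(pset, fr$burial, st$seq, want_param = TRUE)
  recon <- vapply(1:8, function(i)
    sum(ev$basis[i, ] * pset$env[[st$seq[i]]]$coef), 1)
  expect_equal(ev$per_residue, recon, tolerance = 1e-10)
  expect_equal(ev$energy, sum(recon), tolerance = 1e-10)
  # dN is the slope of the per-residue curve at the burial count
  h <- 1e-6
  b2 <- fr$burial; b2[3] <- b2[3] + h
  ev2 <- eval_env(pset, b2, st$seq)
  expect_equal((ev2$energy - ev$energy) / h, ev$dN[3], tolerance = 1e-4)
})
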