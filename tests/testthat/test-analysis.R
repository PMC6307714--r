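test_that("ca_rmsd agrees with an independent quaternion oracle", {
  set.seed(1)
  for (q in 1:5) {
    A <- matrix(rnorm(30, sd = 4), 10, 3)
    B <- A + matrix(rnorm(30, sd = 1), 10, 3)
    expect_equal(ca_rmsd(A, B, exclude_termini = 0), quaternion_rmsd(A, B),
                 tolerance = 1e-8)
  }
})

test_that("ca_rmsd is zero under rigid motion and behaves as a pseudometric", {
  set.seed(2)
  A <- matrix(rnorm(36, sd = 3), 12, 3)
  R <- cgfold:::rotation_about_axis(c(1, -1, 2), 0.9)
  B <- A %*% t(R) + matrix(c(5, 1, -3), 12, 3, byrow = TRUE)
  expect_equal(ca_rmsd(A, B, exclude_termini = 0), 0, tolerance = 1e-9)
  # symmetry and triangle inequality on random frames
  C1 <- A + matrix(rnorm(36), 12, 3)
  C2 <- A + matrix(rnorm(36), 12, 3)
  d12 <- ca_rmsd(C1, C2, exclude_termini = 0)
  expect_equal(d12, ca_rmsd(C2, C1, exclude_termini = 0), tolerance = 1e-10)
  d1A <- ca_rmsd(C1, A, exclude_termini = 0)
  d2A <- ca_rmsd(A, C2, exclude_termini = 0)
  expect_lte(d12, d1A + d2A + 1e-9)
  expect_gte(d12, 0)
})

test_that("terminal exclusion ignores exactly the flexible tails", {
  st <- make_backbone("helix", nres = 12)
  st2 <- st
  # distort only the three terminal residues at each end
  rows <- c(1:9, (36 - 8):36)
  set.seed(3)
  st2$x[rows, ] <- st2$x[rows, ] + matrix(rnorm(length(rows) * 3, sd = 2),
                                          length(rows), 3)
  expect_equal(ca_rmsd(st, st2), 0, tolerance = 1e-9)
  expect_gt(ca_rmsd(st, st2, exclude_termini = 0), 0.5)
  expect_error(ca_rmsd(ca_coords(st), ca_coords(st2)[1:10, ]),
               class = "cg_shape_error")
})

test_that("radius of gyration and the SAW reference behave as documented", {
  # four points at +-1 on two axes: Rg = 1 exactly
  X <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_equal(radius_of_gyration(X), 1, tolerance = 1e-12)
  expect_equal(saw_reference(1), 1.9, tolerance = 1e-12)
  expect_equal(saw_reference(100), 1.9 * 100^0.6, tolerance = 1e-12)
  # a compact helix is denser than the expanded-coil reference
  st <- make_backbone("helix", nres = 30)
  expect_lt(radius_of_gyration(st), saw_reference(30))
})

test_that("heat capacity is the scaled energy variance", {
  set.seed(4)
  e <- rnorm(500, mean = 10, sd = 2)
  expect_equal(heat_capacity(e, 2), var(e) / 4, tolerance = 1e-12)
  expect_equal(heat_capacity(e + 100, 2), heat_capacity(e, 2),
               tolerance = 1e-9)
  expect_error(heat_capacity(1, 1))
})

test_that("hydrogen-bond counting is threshold-monotone and matches helices", {
  st <- make_backbone("helix", nres = 19)
  expect_identical(hbond_count(st), 15L)
  expect_identical(hbond_count(make_backbone("helix", nres = 10)), 6L)
  c1 <- hbond_count(st, threshold = 0.3)
  c2 <- hbond_count(st, threshold = 0.6)
  c3 <- hbond_count(st, threshold = 0.95)
  expect_true(c1 >= c2 && c2 >= c3)
})

test_that("greedy clustering separates basins and orders by size", {
  set.seed(5)
  helix <- make_backbone("helix", nres = 8)
  strand <- make_backbone("strand", nres = 8)
  jitter <- function(st, sd) {
    st$x <- st$x + matrix(rnorm(length(st$x), sd = sd), nrow(st$x), 3)
    st
  }
  frames <- c(lapply(1:5, function(i) jitter(helix, 0.05)),
              lapply(1:2, function(i) jitter(strand, 0.05)),
              lapply(1:3, function(i) jitter(helix, 0.05)))
  cl <- cluster_frames(frames, rmsd_cutoff = 2)
  expect_length(cl$clusters, 2)
  expect_identical(sort(cl$clusters[[1]]), c(1:5, 8:10))
  expect_identical(sort(cl$clusters[[2]]), 6:7)
  expect_identical(cl$assignment[6], cl$assignment[7])
  expect_true(cl$centroids[1] %in% cl$clusters[[1]])
  # one frame, one cluster
  cl1 <- cluster_frames(frames[1])
  expect_length(cl1$clusters, 1)
  expect_identical(cl1$centroids, 1L)
})

test_that("rmsd_histogram discards the first third and bins the rest", {
  ref <- make_backbone("helix", nres = 9)
  set.seed(6)
  frames <- lapply(1:9, function(i) {
    st <- ref
    st$x <- st$x + matrix(rnorm(length(st$x), sd = 0.1 * i), nrow(st$x), 3)
    st
  })
  hh <- rmsd_histogram(frames, ref, discard_fraction = 1 / 3, breaks = 0.5)
  expect_length(hh$rmsd, 6)   # frames 4..9 kept
  expect_identical(sum(hh$counts), 6L)
  expect_true(all(hh$rmsd >= 0))
  # RMSD grows with the applied noise on average
  expect_gt(mean(hh$rmsd[4:6]), mean(hh$rmsd[1:3]) - 0.2)
})

test_that("trajectory_stats assembles the per-frame table", {
  st <- make_backbone("helix", nres = 7)
  frames <- list(st, st)
  ts <- trajectory_stats(frames, reference = st)
  expect_identical(nrow(ts), 2L)
  expect_named(ts, c("frame", "rg", "n_hbond", "rmsd"))
  expect_equal(ts$rmsd, c(0, 0), tolerance = 1e-9)
  expect_identical(ts$n_hbond, c(3L, 3L))
})
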