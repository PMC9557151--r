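test_that("local_helix_axes recovers the axis of an ideal helix", {
  h <- generate_kinked_helix(kinked_helix_params(n_residues = 36,
                                                 kink_angle = 0))
  ax <- local_helix_axes(h)
  expect_equal(nrow(ax$local_axes), 33)
  expect_equal(sqrt(rowSums(ax$local_axes^2)), rep(1, 33), tolerance = 1e-12)
  expect_lt(tilt_angle(ax$axis, c(0, 0, 1)), 0.5)

  # equivariance: rotating the helix rotates the axis identically
  a <- 30 * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  h2 <- helix_trace(h$coords %*% t(Rx), h$resid)
  expect_equal(local_helix_axes(h2)$axis, as.vector(Rx %*% ax$axis),
               tolerance = 1e-9)

  expect_error(suppressWarnings(
    local_helix_axes(helix_trace(cbind(0, 0, 1:4)))), "degenerate")
})

test_that("tilt_angle folds to [0, 90] via the absolute dot product", {
  expect_equal(tilt_angle(c(0, 0, 1)), 0)
  expect_equal(tilt_angle(c(1, 0, 1) / sqrt(2)), 45)
  expect_equal(tilt_angle(c(0, 0, -1)), 0)
  expect_equal(tilt_angle(c(1, 0, 0)), 90)
  expect_error(tilt_angle(c(0, 0, 0)), "zero")
})

test_that("bend_angle measures the apex chord angle", {
  h <- helix_trace(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)),
                   resid = c(123, 130, 134, 141))
  expect_equal(bend_angle(h, 134, c(123, 141)), 180)

  right <- helix_trace(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(5, 5, 5)),
                       resid = c(123, 134, 141, 150))
  expect_equal(bend_angle(right, 134, c(123, 141)), 90)
  expect_error(bend_angle(h, 999, c(123, 141)), "999")

  # reversal symmetry in the two arms
  hk <- generate_kinked_helix(kinked_helix_params(37, kink_residue = 134,
                                                  kink_angle = 20,
                                                  resid_start = 116))
  expect_equal(bend_angle(hk, 134, c(116, 152)),
               bend_angle(hk, 134, c(152, 116)))
})

test_that("bend_angle recovers imposed kinks with full-turn arms", {
  # arms of 18 residues = 5 turns at 100 deg/residue make the apex chords
  # parallel to the local axes, so the chord angle equals 180 - kink exactly
  for (kink in c(5, 15, 30)) {
    p <- kinked_helix_params(n_residues = 37, kink_residue = 134,
                             kink_angle = kink, resid_start = 116)
    expect_equal(bend_angle(generate_kinked_helix(p), 134, c(116, 152)),
                 180 - kink, tolerance = 1e-9)
  }
  # with the TM3 literature residues (123/134/141) the arms span fractional
  # turns and the chords carry a radial offset: a straight helix reads ~173
  h <- generate_kinked_helix(kinked_helix_params(36, kink_angle = 0))
  b <- bend_angle(h, 134, c(123, 141))
  expect_lt(b, 180 - 5)
  expect_gt(b, 165)
})

test_that("kabsch_rmsd removes rigid motion and matches the grid oracle", {
  set.seed(51)
  x <- matrix(rnorm(30), 10)
  expect_equal(kabsch_rmsd(x, x), 0)
  mob <- x %*% t(euler_rot(0.3, 1.1, -0.4))
  expect_lt(kabsch_rmsd(x, sweep(mob, 2, c(4, -2, 9), `+`)), 1e-9)

  y <- x + matrix(rnorm(30, sd = 0.4), 10)
  r <- kabsch_rmsd(x, y)
  expect_equal(r, kabsch_rmsd(y, x), tolerance = 1e-9)
  expect_lte(r, sqrt(mean(rowSums((x - y)^2))))
  # subset restriction
  expect_equal(kabsch_rmsd(x, y, subset = 1:5),
               kabsch_rmsd(x[1:5, ], y[1:5, ]))
  expect_error(kabsch_rmsd(x, y[1:5, ]), "atom count")

  # three seeded cases against the dense-rotation brute force (the
  # acceptance suite runs twenty)
  for (i in 1:3) {
    set.seed(60 + i)
    a <- matrix(rnorm(30), 10)
    b <- a %*% t(euler_rot(runif(1, 0, 2 * pi), runif(1, 0, pi),
                           runif(1, 0, 2 * pi))) +
      matrix(rnorm(30, sd = 0.3), 10)
    expect_equal(kabsch_rmsd(a, b), brute_rmsd(a, b), tolerance = 1e-3)
  }
})

test_that("angle_series averages frames and monomers with sample sd", {
  # two-frame fixture alternating straight and kinked helices
  p0 <- kinked_helix_params(37, kink_residue = 134, kink_angle = 0,
                            resid_start = 116)
  p1 <- kinked_helix_params(37, kink_residue = 134, kink_angle = 20,
                            resid_start = 116)
  h0 <- generate_kinked_helix(p0)$coords
  h1 <- generate_kinked_helix(p1)$coords
  atoms <- data.frame(serial = 1:37, name = "CA", resname = "ALA",
                      chain = "A", resid = 116:152, element = "C",
                      stringsAsFactors = FALSE)
  s <- structure_new(atoms, h0, rep(1L, 37))
  tr <- trajectory(s, list(h0, h1), times = c(0, 60))
  bs <- angle_series(tr, monomers = 1, resid_range = 116:152, type = "bend",
                     apex_residue = 134, end_residues = c(116, 152))
  expect_equal(bs$value_deg, c(180, 160), tolerance = 1e-9)
  expect_equal(bs$mean_deg, 170, tolerance = 1e-9)
  expect_equal(bs$sd_deg, stats::sd(c(180, 160)), tolerance = 1e-9)

  # constant structure: sd exactly zero
  tc <- trajectory(s, list(h0, h0, h0), times = c(0, 60, 120))
  ts <- angle_series(tc, 1, 116:152, type = "tilt")
  expect_equal(ts$sd_deg, 0)

  # two frames at 160 and 170 degrees: mean 165, sample sd ~7.07
  expect_equal(stats::sd(c(160, 170)), 10 / sqrt(2), tolerance = 1e-9)
})

test_that("rmsd_series tracks deviation from the reference frame", {
  set.seed(71)
  coords <- matrix(rnorm(60), 20)
  atoms <- data.frame(serial = 1:20, name = "CA", resname = "GLY",
                      chain = "A", resid = 1:20, element = "C",
                      stringsAsFactors = FALSE)
  s <- structure_new(atoms, coords, rep(1L, 20))
  shift <- matrix(rnorm(60, sd = 0.5), 20)
  tr <- trajectory(s, list(coords, coords + shift), times = c(0, 60))
  rs <- rmsd_series(tr, subset = 1:20)
  expect_equal(rs$rmsd_A[1], 0)
  expect_gt(rs$rmsd_A[2], 0)
  expect_lte(rs$rmsd_A[2], sqrt(mean(rowSums(shift^2))))
})
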