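test_that("resolve_interface expands kinds to the right monomer pairs", {
  s <- toy_contact_structure(18)
  specs <- claudin15_interfaces()

  # intra-monomer salt bridge on an 18-monomer strand -> 18 pairs
  rp <- resolve_interface(specs[["K155-N148"]], s)
  expect_length(rp, 18)
  expect_true(all(vapply(rp, function(p) p$monomers[1] == p$monomers[2],
                         TRUE)))

  # side-by-side contact on one row of 9 monomers -> 8 neighbour pairs
  g <- group_map(list(1:4, 5:8, 9:12, 13:16), rows = list(1:9))
  rc <- resolve_interface(specs[["S67-E157"]], s, g)
  expect_length(rc, 8)
  expect_equal(rc[[3]]$monomers, c(3, 4))

  # R79 sidechain vs F65 backbone subsets resolve to the named atoms
  rb <- resolve_interface(specs[["R79-F65"]], s, monomers = 1)
  expect_equal(sort(s$atoms$name[rb[[1]]$atoms_a]), c("NH1", "NH2"))
  expect_equal(sort(s$atoms$name[rb[[1]]$atoms_b]), c("N", "O"))

  # a residue absent from the structure errors by name
  bad <- interface_spec("X9-F65", 999, 65, kind = "intra")
  expect_error(resolve_interface(bad, s, monomers = 1), "999")
})

test_that("distance_series takes the per-frame minimum over atom pairs", {
  # two single atoms 3 A apart in all frames -> constant series
  s <- point_structure(rbind(c(0, 0, 0), c(3, 0, 0)), monomer = c(1, 2))
  tr <- trajectory(s, list(s$coords, s$coords + 5), times = c(0, 60))
  rp <- list(list(label = "toy", monomers = c(1, 2), atoms_a = 1L,
                  atoms_b = 2L))
  ser <- distance_series(tr, rp)
  expect_equal(ser[[1]]$dist_A, c(3, 3))
  expect_error(distance_series(tr, rp, frames = integer(0)), "empty")

  # closest pair changes between frames; verify against brute force
  set.seed(81)
  sA <- point_structure(matrix(rnorm(24, sd = 4), 8),
                        monomer = rep(1:2, each = 4))
  frames <- lapply(1:6, function(i) matrix(rnorm(24, sd = 4), 8))
  trA <- trajectory(sA, frames)
  rpA <- list(list(label = "mm", monomers = c(1, 2), atoms_a = 1:4,
                   atoms_b = 5:8))
  got <- distance_series(trA, rpA)[[1]]$dist_A
  brute <- vapply(frames, function(xyz) {
    min(apply(xyz[1:4, ], 1, function(a)
      min(sqrt(rowSums(sweep(xyz[5:8, ], 2, a)^2)))))
  }, 1.0)
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("occupancy is the below-cutoff frame fraction", {
  s <- contact_series(c(rep(3, 83), rep(9, 17)))
  expect_equal(occupancy(s, 6)$occupancy, 0.83)
  expect_equal(occupancy(s, Inf)$occupancy, 1)
  # monotone non-decreasing in the cutoff
  occs <- vapply(c(2, 4, 6, 8, 10), function(ct) occupancy(s, ct)$occupancy,
                 1.0)
  expect_true(all(diff(occs) >= 0))

  # per-pair breakdown averages to the total
  s2 <- contact_series(c(rep(3, 40), rep(9, 60)))
  rep2 <- occupancy(list(s, s2), 6)
  expect_equal(rep2$occupancy, mean(c(0.83, 0.40)))
  expect_equal(mean(rep2$per_pair), rep2$occupancy)
})

test_that("occupancy estimator is unbiased on Bernoulli ground truth", {
  occ <- vapply(1:100, function(i) {
    s <- generate_contact_series(contact_gen_params(n_frames = 400, p = 0.6,
                                                    seed = 1000 + i))
    occupancy(s, 6)$occupancy
  }, 1.0)
  expect_lt(abs(mean(occ) - 0.6), 0.01)
})

test_that("distance_distribution quantifies the extended tail", {
  s1 <- generate_contact_series(contact_gen_params(
    n_frames = 5000, p = 0.8, bound_mean = 4, bound_sd = 0.5,
    unbound_mean = 9, unbound_sd = 0.5, seed = 91))
  d1 <- distance_distribution(s1)
  expect_gt(d1$q95_A, 8)
  s2 <- generate_contact_series(contact_gen_params(
    n_frames = 5000, p = 1, bound_mean = 4, bound_sd = 0.5, seed = 92))
  d2 <- distance_distribution(s2)
  expect_lt(d2$q95_A, 5)
  expect_error(distance_distribution(s1, bin_width = 0), "positive")

  # constant series occupies a single bin
  dc <- distance_distribution(contact_series(rep(4.2, 50)))
  expect_equal(sum(dc$histogram$density > 0), 1)
})

test_that("beta_sheet_contact averages registered pair distances", {
  mk_pair <- function(gap) {
    # two 3-residue beta strands, backbone N/O only, facing at `gap` A
    atoms <- data.frame(
      serial = 1:12,
      name = rep(c("N", "O"), 6),
      resname = "VAL",
      chain = rep(c("A", "B"), each = 6),
      resid = rep(rep(60:62, each = 2), 2),
      element = rep(c("N", "O"), 6), stringsAsFactors = FALSE)
    xyz <- rbind(cbind(seq(0, 5, length.out = 6), 0, 0),
                 cbind(seq(0, 5, length.out = 6), gap, 0))
    structure_new(atoms, xyz, rep(1:2, each = 6))
  }
  s <- mk_pair(2.9)
  g <- group_map(list(1:4), pairs = list(c(1, 2)))
  tr <- trajectory(s, list(s$coords, s$coords), times = c(0, 60))
  res <- beta_sheet_contact(tr, g, beta4_resid = 60:62)
  expect_equal(res$mean_A, 2.9, tolerance = 1e-12)
  expect_equal(res$sd_A, 0)

  # one pair at 3.0, one at 3.6 -> mean 3.3: shift frame 2 instead
  tr2 <- trajectory(s, list(mk_pair(3.0)$coords, mk_pair(3.6)$coords),
                    times = c(0, 60))
  res2 <- beta_sheet_contact(tr2, g, beta4_resid = 60:62)
  expect_equal(res2$mean_A, 3.3, tolerance = 1e-12)

  # jittered frames: sd of the frame means reflects the jitter scale
  set.seed(93)
  gaps <- 3 + rnorm(200, sd = 0.1)
  trj <- trajectory(s, lapply(gaps, function(gp) mk_pair(gp)$coords))
  resj <- beta_sheet_contact(trj, g, beta4_resid = 60:62)
  expect_lt(abs(resj$sd_A - 0.1) / 0.1, 0.2)

  # unpaired monomer: warning, pair skipped
  g2 <- group_map(list(1:4), pairs = list(c(1, 2), c(1, 3)))
  expect_warning(beta_sheet_contact(tr, g2, beta4_resid = 60:62),
                 "skipped")
})

test_that("distances are invariant under global rigid motion", {
  set.seed(95)
  s <- point_structure(matrix(rnorm(18, sd = 3), 6),
                       monomer = rep(1:2, each = 3))
  rp <- list(list(label = "r", monomers = c(1, 2), atoms_a = 1:3,
                  atoms_b = 4:6))
  R <- euler_rot(0.4, 0.9, -1.2)
  f1 <- s$coords
  f2 <- sweep(f1 %*% t(R), 2, c(10, -3, 2), `+`)
  tr <- trajectory(s, list(f1, f2), times = c(0, 60))
  ser <- distance_series(tr, rp)[[1]]$dist_A
  expect_equal(ser[1], ser[2], tolerance = 1e-9)
})
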