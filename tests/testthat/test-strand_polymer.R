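test_that("project_trace drops the membrane normal and is equivariant", {
  x <- seq(0, 10, length.out = 5)
  centers <- cbind(x, 2 * x, rnorm(5))
  tr <- project_trace(centers)
  expect_equal(tr$points[, 2], 2 * tr$points[, 1])
  expect_equal(ncol(tr$points), 2L)

  # minimal 3-point input gives one interior tangent
  tp <- tangent_profile(project_trace(cbind(0:2, 0, 0)))
  expect_length(tp$phi, 1)

  # in-plane rotation commutes with projection
  set.seed(5)
  c3 <- cbind(cumsum(runif(6, 1, 2)), rnorm(6), rnorm(6))
  a <- 0.8
  Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  p1 <- project_trace(c3 %*% t(Rz))$points
  p2 <- project_trace(c3)$points %*% t(rot2(a))
  expect_equal(p1, p2, tolerance = 1e-12)

  expect_error(project_trace(cbind(c(0, 0, 1), c(0, 0, 1), 0)),
               "coincident")
})

test_that("tangent_profile computes central-difference angles and ds", {
  # straight chain: all angles 0, ds = spacing
  tp <- tangent_profile(polymer_trace(cbind(seq(0, 12, by = 3), 0)))
  expect_equal(tp$phi, rep(0, 3))
  expect_equal(tp$ds, rep(3, 3))

  # regular polygon: successive angle differences = exterior angle
  m <- 12
  th <- 2 * pi * (0:(m - 1)) / m
  poly <- cbind(cos(th), sin(th))
  tp2 <- tangent_profile(polymer_trace(poly))
  d <- diff(tp2$phi)
  d <- atan2(sin(d), cos(d))  # wrap to (-pi, pi]
  expect_equal(d, rep(2 * pi / m, m - 3), tolerance = 1e-12)

  # alternating spacings 1 and 3 -> half-sum ds = 2
  xs <- cumsum(c(0, rep(c(1, 3), 3)))
  tp3 <- tangent_profile(polymer_trace(cbind(xs, 0)))
  expect_equal(tp3$ds, rep(2, length(xs) - 2))

  # zero tangent (r_{i+1} == r_{i-1}) is an error
  expect_error(tangent_profile(polymer_trace(rbind(c(0, 0), c(1, 0.5),
                                                   c(0, 0)))),
               "zero tangent")
})

test_that("mean_segment_length is the pooled flat average", {
  p1 <- tangent_profile(polymer_trace(cbind(cumsum(c(0, 1, 1, 1, 1)), 0)))
  p2 <- tangent_profile(polymer_trace(cbind(cumsum(c(0, 4, 4, 4)), 0)))
  expect_equal(mean_segment_length(p1), 1)
  # unequal counts: flat average over all ds_i, not mean of frame means
  flat <- mean(c(p1$ds, p2$ds))
  expect_equal(mean_segment_length(list(p1, p2)), flat)
  expect_false(isTRUE(all.equal(flat, mean(c(mean(p1$ds), mean(p2$ds))))))
})

test_that("tangent_correlation pools pairs per lag with C(0) = 1", {
  straight <- lapply(1:4, function(i)
    tangent_profile(polymer_trace(cbind(seq(0, 30, by = 3), i))))
  corr <- tangent_correlation(straight, k_max = 5)
  expect_equal(corr$C, rep(1, 6))
  expect_equal(corr$lag, 0:5)
  expect_true(all(diff(corr$count[-1]) < 0))
  expect_error(tangent_correlation(straight, k_max = 50), "k_max")

  # independent uniform angles decorrelate
  set.seed(31)
  rand <- lapply(1:400, function(i)
    structure(list(phi = runif(30, -pi, pi), ds = rep(1, 29), time_ps = i),
              class = "TangentProfile"))
  cr <- tangent_correlation(rand, k_max = 6)
  expect_lt(max(abs(cr$C[-1])), 0.03)
})

test_that("fit_persistence_length inverts the 2D worm-like-chain decay", {
  ds <- 3
  corr <- structure(list(lag = 0:12,
                         C = exp(-(0:12) * ds / (2 * 150)),
                         count = c(500, rep(400, 12)), n_frames = 10),
                    class = "CorrelationFunction")
  est <- fit_persistence_length(corr, ds)
  expect_equal(est$lp_nm, 150, tolerance = 1e-9)
  expect_equal(est$r2, 1, tolerance = 1e-12)
  expect_equal(est$flag, "ok")
  expect_equal(est$lags_used, 12L)

  # factor-of-2 convention: interpreting the slope without the factor of two
  # (i.e. -1/slope) would double the estimate
  expect_equal(-1 / est$slope, 2 * est$lp_nm, tolerance = 1e-9)

  # perfectly rigid strand: no measurable decay
  corr1 <- structure(list(lag = 0:8, C = rep(1, 9),
                          count = rep(100, 9), n_frames = 5),
                     class = "CorrelationFunction")
  est1 <- fit_persistence_length(corr1, ds)
  expect_equal(est1$flag, "no measurable decay")
  expect_true(is.na(est1$lp_nm))

  # non-positive correlations terminate the usable range
  corr2 <- structure(list(lag = 0:6, C = c(1, 0.8, 0.5, -0.1, 0.4, 0.3, 0.2),
                          count = rep(100, 7), n_frames = 5),
                     class = "CorrelationFunction")
  expect_error(fit_persistence_length(corr2, ds), "too fast")
})

test_that("pipeline recovers generator persistence length (scaled down)", {
  # 2,000 frames keeps the unit suite fast; acceptance runs the full size
  for (lp in c(50, 250)) {
    ens <- generate_wlc_ensemble(wlc_params(n_points = 44, ds = 3, lp = lp,
                                            n_frames = 2000, seed = lp))
    res <- persistence_pipeline(ens, k_max = 12)
    expect_lt(abs(res$estimate$lp_nm / lp - 1), 0.1)
    expect_gte(res$estimate$r2, 0.95)
  }
})

test_that("correlation and fit are invariant under in-plane rigid motion", {
  ens <- generate_wlc_ensemble(wlc_params(n_points = 30, ds = 3, lp = 100,
                                          n_frames = 50, seed = 9))
  moved <- lapply(ens, function(tr)
    polymer_trace(sweep(tr$points %*% t(rot2(1.1)), 2, c(40, -7), `+`),
                  time_ps = tr$time_ps))
  r1 <- persistence_pipeline(ens, k_max = 8)
  r2 <- persistence_pipeline(moved, k_max = 8)
  expect_equal(r1$correlation$C, r2$correlation$C, tolerance = 1e-9)
  expect_equal(r1$estimate$lp_nm, r2$estimate$lp_nm, tolerance = 1e-9)
})
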