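# Surrogate learner: relative-phase flow, fixed points, basins, readout.

test_that("rp_flow has fixed points at 0 and pi with the stated stability", {
  p <- surrogate_params(a = 1, b = 0.25, c = 0)
  expect_equal(rp_flow(0, p), 0)
  expect_equal(rp_flow(pi, p), 0, tolerance = 1e-12)
  # linearization: slope at 0 is -(a + 4b); at pi it is a - 4b, so the
  # anti-phase state gains stability exactly at b = a/4
  eps <- 1e-7
  slope_at <- function(phi, b) {
    pb <- surrogate_params(a = 1, b = b, c = 0)
    (rp_flow(phi + eps, pb) - rp_flow(phi - eps, pb)) / (2 * eps)
  }
  expect_equal(slope_at(0, 0.25), -2, tolerance = 1e-5)
  expect_equal(slope_at(pi, 0.25), 0, tolerance = 1e-5)
  expect_gt(slope_at(pi, 0.2), 0)   # unstable below a/4
  expect_lt(slope_at(pi, 0.3), 0)   # stable above a/4
})

test_that("fixed_points matches a brute-force sign scan", {
  set.seed(99)
  for (i in 1:50) {
    p <- surrogate_params(a = runif(1, 0.2, 2), b = runif(1, 0, 1),
                          c = runif(1, 0, 2),
                          psi_intent_deg = runif(1, -180, 180))
    fp <- fixed_points(p)
    # independent oracle: dense sign scan at 10^4 grid points
    grid <- seq(-pi, pi, length.out = 10001)
    f <- rp_flow(grid, p)
    sc <- which(f[-10001] * f[-1] < 0)
    roots <- (grid[sc] + grid[sc + 1]) / 2
    expect_equal(nrow(fp), length(roots))
    for (r in roots) {
      expect_lt(min(abs(wrap_deg(fp$phi_deg - r * 180 / pi))), 0.5)
    }
  }
})

test_that("fixed-point structure follows the bistability conditions", {
  # bistable regime: two stable states (0 strongly, pi weakly) plus an
  # unstable pair between them
  fp <- fixed_points(surrogate_params(a = 1, b = 0.5, c = 0))
  stable <- fp$phi_deg[fp$stable]
  expect_equal(sort(round(abs(stable))), c(0, 180), ignore_attr = TRUE)
  expect_equal(sum(!fp$stable), 2)
  # monostable when b < a/4
  fp2 <- fixed_points(surrogate_params(a = 1, b = 0.2, c = 0))
  expect_equal(sum(fp2$stable), 1)
  expect_equal(fp2$phi_deg[fp2$stable], 0, tolerance = 1e-6)
  # large intentional coupling pins the flow near the intended phase
  fp3 <- fixed_points(surrogate_params(a = 0.2, b = 0.05, c = 20,
                                       psi_intent_deg = 90))
  st3 <- fp3$phi_deg[fp3$stable]
  expect_equal(length(st3), 1)
  expect_lt(abs(st3 - 90), 5)
})

test_that("default surrogate is bistable with a dominant in-phase basin", {
  p <- surrogate_params()
  set.seed(202)
  phi0 <- runif(200, -pi, pi)
  path <- simulate_rp_flow(p, phi0, duration = 30, dt = 1 / 100, seed = 203)
  tail_rows <- path[(nrow(path) - 500):nrow(path), ]
  endm <- apply(tail_rows, 2, function(v)
    atan2(mean(sin(v)), mean(cos(v)))) * 180 / pi
  d0 <- abs(endm)
  near <- pmin(d0, 180 - d0) <= 10
  expect_gte(mean(near), 0.95)
  # in-phase basin strictly larger (sigma = 0 deterministic basins)
  p0 <- surrogate_params(sigma = 0)
  det <- simulate_rp_flow(p0, seq(-pi, pi, length.out = 181),
                          duration = 40, dt = 1 / 100)
  ends <- abs(det[nrow(det), ]) * 180 / pi
  expect_gt(mean(ends < 90), 0.5)
  expect_gt(mean(ends > 90), 0.1)   # anti-phase basin exists
})

test_that("switches from near anti-phase land at in-phase", {
  p <- surrogate_params(sigma = 0.6)
  path <- simulate_rp_flow(p, rep(170 * pi / 180, 150), duration = 90,
                           dt = 1 / 100, seed = 7)
  ends <- apply(path[(nrow(path) - 500):nrow(path), ], 2, function(v)
    atan2(mean(sin(v)), mean(cos(v)))) * 180 / pi
  expect_gte(mean(abs(ends) < 30), 0.9)
})

test_that("noiseless intentional surrogate locks in phase with the VT", {
  sp <- surrogate_params(sigma = 0, c = 4, psi_intent_deg = 0)
  sched <- structure(
    data.frame(label = "Exposition", duration = 12, C = 0, A = 0, B = 0,
               psi_deg = 0, pacing = FALSE, stringsAsFactors = FALSE),
    class = c("coupling_schedule", "data.frame"), fs = 500)
  tr <- simulate_dyad(sched, surrogate_partner(sp), seed = 4)
  phi_late <- tr$phi[tr$t > 9] * 180 / pi
  expect_lt(abs(circular_mean(phi_late)), 5)
  # and the measured Hilbert RP agrees with the ground-truth phase
  x <- preprocess(tr$x_vt); y <- preprocess(tr$y_partner)
  rp <- continuous_rp(x, y, t = tr$t)
  expect_lt(abs(circular_mean(rp$rp[rp$t > 9 & rp$t < 11])), 5)
})

test_that("scripted partner differentiates traces like the apparatus", {
  # constant trace: zero velocity
  pm <- scripted_partner(rep(0.7, 600))
  expect_true(all(pm$dy == 0))
  # pure 1 Hz cosine: velocity amplitude 2*pi within 1%
  tt <- (0:2999) / 500
  pm2 <- scripted_partner(data.frame(t = tt, y = cos(2 * pi * tt)))
  expect_equal(max(abs(pm2$dy)), 2 * pi, tolerance = 0.01)
})

test_that("surrogate parameter invariants are enforced", {
  expect_error(surrogate_params(a = 0), "positive")
  expect_error(surrogate_params(sigma = -1), "non-negative")
  expect_error(surrogate_params(amplitude = 0), "positive")
})
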