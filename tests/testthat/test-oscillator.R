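# Core virtual-teacher model: force terms, RK4 integrator, limit cycle.

test_that("intrinsic acceleration matches term-by-term evaluation", {
  p <- vt_params(alpha = 1, beta = 1, gamma = 1, omega = 2 * pi)
  # rest point of the unforced flow
  expect_equal(intrinsic_acceleration(oscillator_state(0, 0, 0), p), 0)
  # harmonic-oscillator limit: alpha = beta = 0, tiny gamma
  ph <- vt_params(alpha = 0, beta = 0, gamma = 1e-12, omega = 2 * pi)
  expect_equal(intrinsic_acceleration(oscillator_state(0, 1, 0), ph),
               -(2 * pi)^2, tolerance = 1e-9)
  # frozen value from an independent term-by-term evaluation:
  # -(1*1^3 + 1*0.25*1 - 1*1) - (2*pi)^2*0.5 = -19.98920880217872
  expect_equal(intrinsic_acceleration(oscillator_state(0, 0.5, 1), p),
               -19.98920880217872, tolerance = 1e-12)
  expect_error(intrinsic_acceleration(list(x = NaN, dx = 0), p), "corrupt")
})

test_that("HKB coupling force vanishes where it should", {
  p <- vt_params(A = 0, B = 0)
  st <- oscillator_state(0, 0.3, -0.7)
  expect_equal(hkb_coupling_force(st, human_observation(0.9, 2), p), 0)
  p2 <- vt_params(A = 1, B = 1, mu = 2)
  # perfect in-phase after scaling: x = mu y, dx = mu dy
  expect_equal(hkb_coupling_force(oscillator_state(0, 1, 0.4),
                                  human_observation(0.5, 0.2), p2), 0)
  # static anti-phase snapshot: velocity difference zero
  p3 <- vt_params(A = 1, B = 1, mu = 1)
  expect_equal(hkb_coupling_force(oscillator_state(0, 1, 0),
                                  human_observation(-1, 0), p3), 0)
})

test_that("intentional force follows the printed form", {
  p <- vt_params()
  st <- oscillator_state(0, 0.2, 1.5)
  obs <- human_observation(0.8, -0.4)
  expect_equal(intentional_force(st, obs, p, intentional_setting(0, 123)), 0)
  # psi = 0 reduces to velocity coupling
  expect_equal(intentional_force(st, obs, p, intentional_setting(-3, 0)),
               -3 * (1.5 - (-0.4)))
  # psi = 90 with matched velocities leaves only the position term
  obs2 <- human_observation(0.8, 1.5)
  expect_equal(intentional_force(st, obs2, p, intentional_setting(2, 90)),
               2 * p$omega * 0.8, tolerance = 1e-12)
})

test_that("vt_derivative is the sum of its three components", {
  p <- vt_params()
  s <- intentional_setting(-10, 72)
  st <- oscillator_state(0, 0.43, -1.1)
  obs <- human_observation(-0.3, 2.2)
  d <- vt_derivative(st, obs, p, s)
  expect_equal(d$dx, st$dx)
  expect_equal(d$ddx,
               intrinsic_acceleration(st, p) +
                 hkb_coupling_force(st, obs, p) +
                 intentional_force(st, obs, p, s))
  # decoupled: acceleration independent of the observation
  s0 <- intentional_setting(0, 0)
  p0 <- vt_params(A = 0, B = 0)
  d1 <- vt_derivative(st, human_observation(0, 0), p0, s0)
  d2 <- vt_derivative(st, human_observation(5, -3), p0, s0)
  expect_equal(d1$ddx, d2$ddx)
  # y = dy = 0 kills the position term of the intentional force
  sC <- intentional_setting(-4, 63)
  dz <- vt_derivative(st, human_observation(0, 0), p0, sC)
  expect_equal(dz$ddx, intrinsic_acceleration(st, p0) +
                 -4 * st$dx * cos(63 * pi / 180))
})

test_that("RK4 reproduces the harmonic oscillator and is 4th order", {
  # disable all damping and coupling: pure harmonic limit, closed-form
  p <- vt_params(alpha = 0, beta = 0, gamma = 1e-300, omega = 2 * pi,
                 A = 0, B = 0)
  s <- intentional_setting(0, 0)
  obs <- human_observation(0, 0)
  dt <- 1 / 500
  st <- oscillator_state(0, 1, 0)
  for (i in seq_len(500)) st <- rk4_step(st, obs, p, s, dt)
  expect_equal(st$x, 1, tolerance = 1e-6)
  expect_equal(st$dx, 0, tolerance = 1e-4)

  # empirical convergence order from one-period errors at dt and dt/2,
  # in the phase-space norm (the position error alone is second order in
  # the phase error at the cycle extremum)
  err_at <- function(dt) {
    st <- oscillator_state(0, 1, 0)
    for (i in seq_len(round(1 / dt))) st <- rk4_step(st, obs, p, s, dt)
    sqrt((st$x - 1)^2 + (st$dx / (2 * pi))^2)
  }
  order <- log2(err_at(1 / 250) / err_at(1 / 500))
  expect_gt(order, 3.8)
  expect_lt(order, 4.2)

  expect_error(rk4_step(st, obs, p, s, 0), "dt must be positive")
})

test_that("calibrated oscillator has a 1 s, unit-amplitude limit cycle", {
  p <- vt_params()
  set.seed(42)
  for (i in 1:5) {
    x0 <- runif(1, -2, 2); dx0 <- runif(1, -2, 2)
    if (abs(x0) < 0.05 && abs(dx0) < 0.05) x0 <- 0.5
    m <- measure_limit_cycle(p, x0 = x0, dx0 = dx0)
    expect_equal(m$period, 1, tolerance = 0.02)
    expect_equal(m$amplitude, 1, tolerance = 0.05)
  }
  # near-sinusoidal waveform
  expect_lt(measure_limit_cycle(p)$thd, 0.05)
})

test_that("calibrate_vt reproduces the stored defaults", {
  p <- calibrate_vt()
  d <- vt_params()
  expect_equal(p$alpha, d$alpha, tolerance = 1e-4)
  expect_equal(p$beta, d$beta, tolerance = 1e-4)
  expect_equal(p$omega, d$omega, tolerance = 1e-4)
})

test_that("parameter validation rejects non-sustaining configurations", {
  expect_error(vt_params(gamma = 0), "gamma")
  expect_error(vt_params(alpha = -1), "non-negative")
  expect_error(vt_params(mu = 0), "mu")
  expect_error(intentional_setting(NaN, 0), "is.finite")
})
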