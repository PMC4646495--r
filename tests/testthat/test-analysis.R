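# Data-reduction pipeline: preprocessing, Hilbert RP, segmentation,
# circular statistics, constant error.

test_that("preprocessing is transparent for a clean 1 Hz cosine", {
  fs <- 500
  tt <- (0:4999) / fs
  v <- cos(2 * pi * tt)
  out <- preprocess(v, fs)
  mid <- 500:4500  # away from filter edges
  expect_lt(max(abs(out[mid] - v[mid])), 0.01)
  # phase shift below half a degree (zero-phase filtering)
  cc <- stats::ccf(out, v, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("linear drift is removed and flat signals are rejected", {
  fs <- 500
  tt <- (0:4999) / fs
  v <- cos(2 * pi * tt) + 0.5 * tt
  out <- preprocess(v, fs)
  slope <- stats::coef(stats::lm(out ~ tt))[2]
  expect_lt(abs(slope), 1e-3)
  expect_error(preprocess(rep(1, 5000), fs), "cycles")
  expect_error(preprocess(cos(2 * pi * (0:400) / fs), fs), "2 s")
})

test_that("cycle-wise normalization rescales varying amplitudes into [-1,1]", {
  fs <- 500
  tt <- (0:9999) / fs
  v <- (1 + 0.5 * sin(0.3 * tt)) * cos(2 * pi * tt)
  out <- preprocess(v, fs)
  expect_lte(max(abs(out)), 1 + 1e-9)
  # every half cycle touches its extremum
  expect_gt(mean(abs(out) > 0.98), 0.03)
})

test_that("Hilbert relative phase recovers imposed lags within 2 degrees", {
  fs <- 500
  tt <- (0:14999) / fs
  x <- cos(2 * pi * tt)
  for (lag in seq(0, 180, by = 15)) {
    y <- cos(2 * pi * tt - lag * pi / 180)  # partner lags by `lag`
    rp <- continuous_rp(preprocess(x, fs), preprocess(y, fs), t = tt)
    mid <- rp$rp[tt > 2 & tt < 28]
    expect_lt(abs(constant_error(circular_mean(mid), lag)), 2)
  }
  # identity and anti-phase limits
  rp0 <- continuous_rp(x, x)
  expect_lt(max(abs(rp0$rp[2000:13000])), 1e-6)
  expect_lt(circular_variance(rp0$rp[2000:13000]), 1e-10)
  rp180 <- continuous_rp(preprocess(x, fs), preprocess(-x, fs))
  expect_lt(abs(abs(circular_mean(rp180$rp[2000:13000])) - 180), 0.5)
  expect_error(continuous_rp(x, x[-1]), "lengths differ")
})

test_that("sign convention: a lagging partner gives positive RP", {
  fs <- 500
  tt <- (0:9999) / fs
  x <- cos(2 * pi * tt)
  y <- cos(2 * pi * tt - pi / 2)  # partner peaks a quarter cycle later
  rp <- continuous_rp(preprocess(x, fs), preprocess(y, fs))
  expect_equal(circular_mean(rp$rp[2000:8000]), 90, tolerance = 1)
  rp_flip <- continuous_rp(preprocess(x, fs), preprocess(y, fs),
                           convention = "partner_minus_vt")
  expect_equal(circular_mean(rp_flip$rp[2000:8000]), -90, tolerance = 1)
})

test_that("trimming and segmentation produce 20/5/5 s segments", {
  sched <- make_scanning_trial(90)
  fs <- 500
  tt <- (0:(37 * fs - 1)) / fs
  rp <- data.frame(t = tt, rp = rep(0, length(tt)))
  seg <- trim_and_segment(rp, sched, fs)
  expect_equal(nrow(seg$Exposition), 10000)
  expect_equal(nrow(seg$M1), 2500)
  expect_equal(nrow(seg$M2), 2500)
  # M1 ends exactly where M2 begins for an 11 s Memory period
  expect_equal(max(seg$M1$t) + 1 / fs, min(seg$M2$t))
  expect_error(trim_and_segment(rp[tt < 30, ], sched, fs), "shorter")
})

test_that("circular statistics match closed forms", {
  expect_equal(circular_mean(rep(90, 10)), 90)
  expect_equal(circular_variance(rep(90, 10)), 0)
  # two-point resultant: mean 45, variance 1 - cos(45 deg)
  expect_equal(circular_mean(c(0, 90)), 45)
  expect_equal(circular_variance(c(0, 90)), 1 - cos(pi / 4))
  # angles spread uniformly: variance -> 1
  expect_gt(circular_variance(seq(-179, 180, by = 1)), 0.99)
  # wrapping stays in (-180, 180]
  expect_equal(circular_mean(c(170, -170)), 180)
})

test_that("constant error uses the nearer of the pattern and its mirror", {
  expect_equal(constant_error(-90, 90), 0)
  expect_equal(constant_error(100, 90), 10)
  expect_equal(constant_error(100, 90, signed = FALSE), 10)
  expect_equal(constant_error(80, 90), -10)
  expect_equal(abs(constant_error(0, 180)), 180)
  expect_equal(constant_error(-80, 90), 10)   # closer to -90 image
  # bounds
  set.seed(1)
  prod <- runif(200, -180, 180); psi <- runif(200, 0, 180)
  ce <- constant_error(prod, psi)
  expect_true(all(ce >= -180 & ce <= 180))
  expect_true(all(constant_error(prod, psi, signed = FALSE) >= 0))
  expect_true(all(constant_error(prod, psi, signed = FALSE) <= 180))
})

test_that("full pipeline recovers a constructed phase offset per segment", {
  tr <- locked_trial(90)
  res <- analyze_trial(tr)
  expect_equal(nrow(res), 3)
  expect_true(all(abs(res$circ_mean - 90) < 3))
  expect_true(all(res$abs_ce < 3))
  expect_true(all(res$circ_var < 1e-3))
  expect_equal(res$n, c(10000, 2500, 2500))
})
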