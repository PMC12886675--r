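test_that("amperometric steady state follows the linear law", {
  p <- default_channel_params(noiseless = TRUE)$glucose
  zero <- channel_params("glucose", "amperometric", slope = 0.1122,
                         intercept = 0, linear_range = c(0, 20))
  expect_equal(steady_state(amperometric_forward(0, zero, 60), 30), 0)
  expect_equal(steady_state(amperometric_forward(1, p, 60), 30), 0.1122,
               tolerance = 1e-12)
  r10 <- steady_state(amperometric_forward(10, p, 60), 30)
  r5 <- steady_state(amperometric_forward(5, p, 60), 30)
  expect_equal(r10 / r5, 2, tolerance = 1e-12)
})

test_that("noiseless amperometric response is strictly increasing in range", {
  for (ch in c("glucose", "ua", "cholesterol")) {
    p <- default_channel_params(noiseless = TRUE)[[ch]]
    grid <- seq(p$linear_range[1], p$linear_range[2], length.out = 15)
    y <- vapply(grid, function(c_) {
      steady_state(amperometric_forward(c_, p, 10), 5)
    }, numeric(1))
    expect_true(all(diff(y) > 0), info = ch)
  }
})

test_that("out-of-range concentrations saturate at the range edge", {
  p <- default_channel_params(noiseless = TRUE)$glucose
  tr <- amperometric_forward(25, p, 60)
  expect_true(all(tr$saturated))
  expect_equal(steady_state(tr, 30), 0.1122 * 20, tolerance = 1e-12)
  expect_false(any(amperometric_forward(5, p, 60)$saturated))
})

test_that("potentiometric response obeys the Nernstian decade law", {
  pars <- default_channel_params(noiseless = TRUE)
  # at the reference concentration (1 mM, inside the K+ range) the
  # potential equals the intercept
  e_ref <- steady_state(potentiometric_forward(1, pars$k, 60), 30)
  expect_equal(e_ref, pars$k$intercept, tolerance = 1e-12)
  # one decade = one slope, at any anchor in range
  for (c0 in c(5, 8, 12)) {
    d <- steady_state(potentiometric_forward(10 * c0, pars$na, 60), 30) -
      steady_state(potentiometric_forward(c0, pars$na, 60), 30)
    expect_equal(d, 52.87, tolerance = 1e-9)
  }
  # K+: 1 -> 32 mM spans log10(32) decades
  dk <- steady_state(potentiometric_forward(32, pars$k, 60), 30) -
    steady_state(potentiometric_forward(1, pars$k, 60), 30)
  expect_equal(dk, 58.46 * log10(32), tolerance = 1e-9)
  expect_equal(dk, 87.99, tolerance = 1e-4)
  expect_error(potentiometric_forward(0, pars$na, 60), "positive")
})

test_that("pH channel potential falls linearly with pH", {
  p <- default_channel_params(noiseless = TRUE)$ph
  e4 <- steady_state(potentiometric_forward(4, p, 60), 30)
  e5 <- steady_state(potentiometric_forward(5, p, 60), 30)
  expect_equal(e4 - e5, 57.61, tolerance = 1e-9)
})

test_that("interference is additive and bounded for the default panel", {
  pars <- default_channel_params()
  expect_identical(apply_interference(5, numeric(), pars$glucose), 0)
  one <- channel_params("glucose", "amperometric", slope = 1,
                        interference_coeffs = c(x = 0.001),
                        linear_range = c(0, 20))
  expect_equal(apply_interference(5, c(x = 300), one), 0.3)
  expect_error(apply_interference(5, c(mystery = 1), pars$glucose),
               "unknown interferent")
  expect_error(apply_interference(5, c(uric_acid = -1), pars$glucose),
               "non-negative")
  # relative drift of the full standard panel stays within 6% per channel
  mid <- c(glucose = 5, ua = 300, cholesterol = 4, na = 140, k = 4, ph = 7)
  for (ch in names(pars)) {
    p <- pars[[ch]]
    delta <- apply_interference(mid[[ch]], default_interferent_panel(ch), p)
    rel <- abs(delta) / (p$slope * mid[[ch]])
    expect_lte(rel, 0.06)
  }
})

test_that("drift and motion artifacts transform traces as specified", {
  p <- default_channel_params(noiseless = TRUE)$glucose
  tr <- amperometric_forward(5, p, duration_s = 120)
  expect_identical(add_artifacts(tr)$y, tr$y)
  dr <- add_artifacts(tr, drift_rate = 1)
  expect_equal(dr$y[nrow(dr)] - dr$y[1], 2, tolerance = 1e-12)
  # spike scenarios with a 4:1 amplitude ratio measure as ~4:1 peak-to-peak
  noisy <- default_channel_params()$glucose
  base <- amperometric_forward(5, noisy, duration_s = 300, seed = 7)
  big <- add_artifacts(base, motion = list(amplitude = 2, times = c(100, 200)))
  small <- add_artifacts(base, motion = list(amplitude = 0.5,
                                             times = c(100, 200)))
  ptp <- function(tr) diff(range(tr$y - base$y))
  expect_equal(ptp(big) / ptp(small), 4, tolerance = 0.05)
})

test_that("steady_state extracts the trailing-window mean", {
  tr <- sensor_trace("glucose", 0:99, rep(5, 100), "uA_cm2")
  expect_equal(steady_state(tr, 50), 5)
  expect_error(steady_state(tr, 200), "exceeds")
  # exponential transient decaying to an asymptote of 2
  p <- channel_params("glucose", "amperometric", slope = 1,
                      intercept = 0, linear_range = c(0, 20))
  tr2 <- amperometric_forward(2, p, duration_s = 120,
                              transient_amplitude = 3, settle_s = 30)
  expect_equal(steady_state(tr2, 30), 2, tolerance = 1e-3)
  # pure-noise readout concentrates as 1/sqrt(n)
  pn <- channel_params("glucose", "amperometric", slope = 1,
                       noise_sd = 0.5, linear_range = c(0, 20))
  tr3 <- amperometric_forward(0, pn, duration_s = 400, seed = 42)
  n_win <- sum(tr3$t_s >= max(tr3$t_s) - 300)
  expect_lt(abs(steady_state(tr3, 300)), 4 * 0.5 / sqrt(n_win))
})

test_that("stochastic traces are reproducible under a fixed seed", {
  p <- default_channel_params()$ua
  a <- amperometric_forward(500, p, 60, seed = 123)
  b <- amperometric_forward(500, p, 60, seed = 123)
  c <- amperometric_forward(500, p, 60, seed = 124)
  expect_identical(a$y, b$y)
  expect_false(identical(a$y, c$y))
})

test_that("channel params validate and round-trip through YAML", {
  expect_error(channel_params("glucose", "amperometric", slope = -1,
                              linear_range = c(0, 20)), "positive")
  expect_error(channel_params("glucose", "amperometric", slope = 1,
                              linear_range = c(5, 2)), "lo < hi")
  pars <- default_channel_params()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_channel_params(pars, path)
  back <- read_channel_params(path)
  expect_equal(back$na$slope, pars$na$slope)
  expect_equal(back$glucose$interference_coeffs,
               pars$glucose$interference_coeffs)
})
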