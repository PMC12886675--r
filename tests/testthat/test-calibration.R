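test_that("exact lines are recovered exactly", {
  cv <- fit_amperometric(c(0, 1, 2), c(0, 2, 4))
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$r, 1)
  expect_equal(cv$sigma, 0)
  expect_error(fit_amperometric(c(1, 1, 1), c(0, 1, 2)), "identical")
  expect_error(fit_amperometric(c(1, 2), c(0, 1)), "at least 3")
})

test_that("noiseless twin ladders return the generating sensitivities", {
  curves <- calibrate_all_channels(noiseless = TRUE)
  truth <- c(glucose = 0.1122, ua = 0.001395, cholesterol = 0.1637,
             na = 52.87, k = 58.46, ph = -57.61)
  for (ch in names(truth)) {
    expect_equal(curves[[ch]]$slope, truth[[ch]], tolerance = 1e-9,
                 info = ch)
    expect_equal(abs(curves[[ch]]$r), 1, tolerance = 1e-9, info = ch)
  }
})

test_that("OLS fits agree with the stats::lm oracle on random instances", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- runif(n, 0, 10)
    y <- runif(1, -2, 2) + runif(1, 0.1, 5) * x + rnorm(n, 0, 0.3)
    cv <- fit_amperometric(x, y)
    or <- stats::lm(y ~ x)
    expect_equal(cv$slope, unname(coef(or)[2]), tolerance = 1e-9)
    expect_equal(cv$intercept, unname(coef(or)[1]), tolerance = 1e-9)
    expect_equal(cv$sigma, summary(or)$sigma, tolerance = 1e-9)
    expect_equal(cv$r, unname(cor(x, y)), tolerance = 1e-9)
  }
})

test_that("potentiometric fits regress on log10 concentration or pH", {
  conc <- c(1, 10, 100)
  cv <- fit_potentiometric(conc, c(0, 59.16, 118.32))
  expect_equal(cv$slope, 59.16, tolerance = 1e-9)
  expect_equal(cv$r, 1)
  conc2 <- c(5, 10, 20, 40, 80, 160)
  cv2 <- fit_potentiometric(conc2, 250 + 52.87 * log10(conc2),
                            channel = "na")
  expect_equal(cv2$slope, 52.87, tolerance = 1e-9)
  ph <- 3:8
  cv3 <- fit_potentiometric(ph, 600 - 57.61 * ph, modality = "ph")
  expect_equal(abs(cv3$slope), 57.61, tolerance = 1e-9)
  expect_equal(abs(cv3$r), 1, tolerance = 1e-12)
  expect_error(fit_potentiometric(c(-1, 1, 10), c(0, 1, 2)), "positive")
})

test_that("LOD formula and its homogeneity hold", {
  expect_equal(compute_lod(1, 3.3), 1.0)
  expect_equal(compute_lod(0, 5), 0)
  expect_equal(compute_lod(0.02, 0.1122), 3.3 * 0.02 / 0.1122)
  expect_equal(compute_lod(0.02, 0.1122), 0.5882, tolerance = 1e-4)
  for (k in c(0.1, 2, 100)) {
    expect_equal(compute_lod(k * 0.3, k * 1.7), compute_lod(0.3, 1.7))
  }
  expect_error(compute_lod(1, 0), "positive")
  expect_error(compute_lod(-1, 1), "non-negative")
  # the default channel noise reproduces the device's printed LODs
  pars <- default_channel_params()
  expect_equal(compute_lod(pars$glucose$noise_sd, pars$glucose$slope), 0.39)
  expect_equal(compute_lod(pars$ua$noise_sd, pars$ua$slope), 2.7)
  expect_equal(compute_lod(pars$cholesterol$noise_sd,
                           pars$cholesterol$slope), 0.52)
})

test_that("inverse_concentration is the exact algebraic inverse", {
  cv <- fit_amperometric(0:10, 2 * (0:10))
  expect_equal(as.numeric(inverse_concentration(cv, 4)), 2)
  # two decades above the 1 mM anchor
  ion <- fit_potentiometric(c(1, 10, 100), c(0, 59.16, 118.32))
  expect_equal(as.numeric(inverse_concentration(ion, 118.32)), 100,
               tolerance = 1e-9)
  # forward -> fit -> inverse round trip, every channel, noiseless
  pars <- default_channel_params(noiseless = TRUE)
  curves <- calibrate_all_channels(noiseless = TRUE)
  probe <- c(glucose = 7.3, ua = 432, cholesterol = 3.1, na = 77,
             k = 6.4, ph = 5.5)
  for (ch in names(pars)) {
    p <- pars[[ch]]
    f <- if (p$modality == "amperometric") amperometric_forward else
      potentiometric_forward
    readout <- steady_state(f(probe[[ch]], p, 60), 30)
    expect_equal(as.numeric(inverse_concentration(curves[[ch]], readout)),
                 probe[[ch]], tolerance = 1e-9, info = ch)
  }
  expect_warning(inverse_concentration(cv, 1000), "outside")
})

test_that("slope CIs cover the truth at the nominal rate under noise", {
  # 200 seeded replicates of a noisy glucose ladder; the 95% CI of the
  # fitted slope should contain the generating slope ~95% of the time
  set.seed(2024)
  conc <- seq(0, 20, 2)
  slope <- 0.1122
  hits <- 0L
  for (rep in 1:200) {
    y <- slope * conc + rnorm(length(conc), 0, 0.013)
    fit <- stats::lm(y ~ conc)
    ci <- stats::confint(fit)["conc", ]
    cv <- fit_amperometric(conc, y)
    # package fit must match the lm point estimate it is compared against
    expect_equal(cv$slope, unname(coef(fit)[2]), tolerance = 1e-9)
    if (slope >= ci[1] && slope <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.93)
  expect_lte(hits / 200, 0.97)
})

test_that("curves serialize to JSON and tidy/glance report the fit", {
  cv <- fit_amperometric(0:10, 0.1637 * (0:10), channel = "cholesterol")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cv, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$cholesterol$slope, 0.1637, tolerance = 1e-12)
  expect_equal(glance(cv)$slope, 0.1637, tolerance = 1e-12)
  expect_equal(tidy(cv)$estimate[2], 0.1637, tolerance = 1e-12)
})
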