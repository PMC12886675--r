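test_that("severity is a deterministic per-group ramp", {
  cfg <- cohort_config()
  expect_equal(severity("CON", 0, cfg), 0)
  expect_equal(severity("CON", 4, cfg), 0)
  expect_equal(severity("HFFD", 0, cfg), 0)
  expect_equal(severity("HFFSD", 4, cfg), 1)
  expect_equal(severity("HFFD", 2, cfg), 0.7 * 2 / 4)
  # monotone non-decreasing in week, HFFSD >= HFFD at equal week
  for (w in 0:3) {
    expect_gte(severity("HFFD", w + 1, cfg), severity("HFFD", w, cfg))
    expect_gte(severity("HFFSD", w, cfg), severity("HFFD", w, cfg))
  }
  expect_error(severity("HG", 1, cfg), "unknown group")
  expect_error(severity("HFFD", 9, cfg), "must lie in")
})

test_that("simulate_chronic emits n_per_group x groups x (weeks+1) panels", {
  panels <- simulate_chronic(cohort_config(n_per_group = 10, seed = 4))
  expect_equal(nrow(panels), 10 * 3 * 5)
  expect_setequal(unique(panels$group), c("CON", "HFFD", "HFFSD"))
  expect_equal(sort(unique(panels$week)), 0:4)
  # every subject is measured once per week
  counts <- table(panels$subject_id)
  expect_true(all(counts == 5))
})

test_that("identical config and seed give bit-identical cohorts", {
  a <- simulate_chronic(cohort_config(n_per_group = 5, seed = 99))
  b <- simulate_chronic(cohort_config(n_per_group = 5, seed = 99))
  c <- simulate_chronic(cohort_config(n_per_group = 5, seed = 100))
  expect_identical(a$glucose_mM, b$glucose_mM)
  expect_identical(a$degree, b$degree)
  expect_false(identical(a$glucose_mM, c$glucose_mM))
})

test_that("control group stays at baseline and degree near zero", {
  cfg <- cohort_config(n_per_group = 200, seed = 8)
  panels <- simulate_chronic(cfg)
  con4 <- panels[panels$group == "CON" & panels$week == 4, ]
  # empirical mean within 3 SE of the configured baseline
  se <- cfg$baseline_sds[["glucose"]] * sqrt(1.25 / nrow(con4))
  expect_lt(abs(mean(con4$glucose_mM) - cfg$baseline_means[["glucose"]]),
            3 * se)
  con <- panels[panels$group == "CON", ]
  expect_lt(mean(con$degree), 0.05)
})

test_that("mean degree strictly increases with week in the diet groups", {
  panels <- simulate_chronic(cohort_config(n_per_group = 30, seed = 13))
  for (g in c("HFFD", "HFFSD")) {
    m <- tapply(panels$degree[panels$group == g],
                panels$week[panels$group == g], mean)
    expect_true(all(diff(m) > 0), info = g)
  }
})

test_that("zero-effect groups are statistically exchangeable", {
  # over repeated simulations the one-way ANOVA p-value for any channel is
  # uniform; its mean should hover around 0.5
  ps <- vapply(1:40, function(i) {
    panels <- simulate_chronic(null_cohort_config(n_per_group = 6,
                                                  seed = 1000 + i))
    w4 <- panels[panels$week == 4, ]
    summary(stats::aov(glucose_mM ~ group, data = w4))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("every emitted panel satisfies the range invariants", {
  # inflated noise forces clipping; values must still respect the ranges
  cfg <- cohort_config(n_per_group = 40, seed = 3)
  cfg$baseline_sds <- cfg$baseline_sds * 12
  panels <- suppressMessages(simulate_chronic(cfg))
  expect_gt(attr(panels, "clipped"), 0)
  rng <- list(glucose_mM = c(0, 20), ua_uM = c(0, 1000),
              cholesterol_mM = c(0, 10), na_mM = c(5, 160),
              k_mM = c(1, 32), ph = c(3, 8))
  for (col in names(rng)) {
    expect_true(all(panels[[col]] >= rng[[col]][1] &
                      panels[[col]] <= rng[[col]][2]), info = col)
  }
  expect_true(all(panels$degree >= 0 & panels$degree <= 1))
})

test_that("impossible effect shifts fail fast naming the channel", {
  rates <- default_effect_rates()
  rates$HFFSD[["glucose"]] <- 10   # week-4 mean would exceed 20 mM
  expect_error(cohort_config(effect_rates = rates), "glucose")
  expect_error(cohort_config(baseline_means = c(glucose = 9, ua = 295,
                                                cholesterol = 4, na = 140,
                                                k = 4.2, ph = 7.1)),
               "physiological")
  expect_error(cohort_config(glucose_cholesterol_rho = 1.4), "rho")
})

test_that("panels round-trip through CSV with manifest", {
  panels <- simulate_chronic(cohort_config(n_per_group = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_panels(panels, path, config = cohort_config(n_per_group = 3,
                                                    seed = 2))
  back <- read_panels(path)
  expect_equal(back$glucose_mM, panels$glucose_mM, tolerance = 1e-12)
  expect_equal(names(back), names(panels))
  manifest <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(manifest$n_panels, nrow(panels))
})
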