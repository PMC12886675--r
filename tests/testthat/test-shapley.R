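test_that("Shapley values of additive functions equal their coefficients", {
  f <- function(m) 2 * m[1, 1] + 3 * m[2, 1]
  phi <- exact_shapley(f, c(1, 1, 0, 0, 0, 0), numeric(6))
  expect_equal(unname(as.numeric(phi)), c(2, 3, 0, 0, 0, 0),
               tolerance = 1e-12)
})

test_that("dummy, symmetry and linearity axioms hold", {
  x <- c(1, 1, 2, 0.5, -1, 3)
  base <- numeric(6)
  # dummy: an ignored channel gets zero
  f_dummy <- function(m) m[1, 1]^2 + exp(m[3, 1])
  phi <- exact_shapley(f_dummy, x, base)
  expect_equal(unname(phi[c(2, 4, 5, 6)]), rep(0, 4), tolerance = 1e-12)
  # symmetry: interchangeable channels with equal values get equal phi
  f_sym <- function(m) m[1, 1] * m[2, 1] + m[1, 1] + m[2, 1]
  phi_s <- exact_shapley(f_sym, c(1, 1, 0, 0, 0, 0), base)
  expect_equal(unname(phi_s[1]), unname(phi_s[2]), tolerance = 1e-12)
  # linearity: phi of f + g equals phi_f + phi_g
  set.seed(6)
  a <- rnorm(6); b <- rnorm(6)
  f <- function(m) sum(a * m[, 1]) + m[1, 1] * m[2, 1]
  g <- function(m) sum(b * m[, 1]^2)
  fg <- function(m) f(m) + g(m)
  expect_equal(as.numeric(exact_shapley(fg, x, base)),
               as.numeric(exact_shapley(f, x, base)) +
                 as.numeric(exact_shapley(g, x, base)),
               tolerance = 1e-9)
})

test_that("efficiency holds for arbitrary nonlinear heads", {
  set.seed(7)
  for (rep in 1:5) {
    w1 <- matrix(rnorm(36), 6, 6)
    f <- function(m) {
      v <- rowSums(m)
      sum(tanh(w1 %*% v)) + max(v)
    }
    x <- matrix(rnorm(18), 6, 3)
    base <- matrix(rnorm(18, sd = 0.1), 6, 3)
    phi <- exact_shapley(f, x, base)
    expect_equal(sum(phi), attr(phi, "f_x") - attr(phi, "f_baseline"),
                 tolerance = 1e-6)
  }
})

test_that("sampled estimator agrees with exact enumeration within 3 SE", {
  set.seed(8)
  w1 <- matrix(rnorm(36, sd = 0.5), 6, 6)
  f <- function(m) sum(sin(w1 %*% m[, 1])) + prod(1 + 0.1 * m[1:3, 1])
  x <- rnorm(6); base <- numeric(6)
  exact <- as.numeric(exact_shapley(f, x, base))
  samp <- sampled_shapley(f, x, base, n_permutations = 300, seed = 11)
  expect_true(all(abs(samp$phi - exact) <= 3 * pmax(samp$se, 1e-12)))
  expect_error(sampled_shapley(f, x, base, n_permutations = 5), "at least 10")
})

test_that("deduplicated full enumeration reproduces the exact values", {
  set.seed(9)
  f <- function(m) sum(m[, 1]^2) + m[1, 1] * m[4, 1]
  x <- rnorm(6); base <- rnorm(6, sd = 0.2)
  exact <- as.numeric(exact_shapley(f, x, base))
  full <- sampled_shapley(f, x, base, n_permutations = factorial(6),
                          dedup = TRUE)
  expect_equal(full$phi, exact, tolerance = 1e-10)
  # seed determinism of the sampling path
  s1 <- sampled_shapley(f, x, base, n_permutations = 50, seed = 3)
  s2 <- sampled_shapley(f, x, base, n_permutations = 50, seed = 3)
  expect_identical(s1$phi, s2$phi)
})

test_that("non-finite model outputs abort with the coalition named", {
  f <- function(m) if (m[2, 1] > 0.5) NaN else sum(m)
  expect_error(exact_shapley(f, rep(1, 6), numeric(6)), "coalition")
})

test_that("model attributions satisfy efficiency on every window and head", {
  cv <- small_cv()
  fx <- small_windows()
  rep1 <- shap_report(cv$models[[1]], fx$windows[1:6, ], max_windows = 6)
  eff <- rep1 |>
    dplyr::group_by(.data$window_id, .data$head) |>
    dplyr::summarise(gap = abs(sum(.data$phi) -
                                 (.data$f_x[1] - .data$f_baseline[1])),
                     .groups = "drop")
  expect_lt(max(eff$gap), 1e-6)
})

test_that("attribution summary ranks generator-driven channels on top", {
  cv <- small_cv()
  fx <- small_windows()
  val <- which(fx$folds$assignments == 1)
  rep1 <- shap_report(cv$models[[1]], fx$windows[val, ], max_windows = 40,
                      seed = 2)
  sm <- shap_summary(rep1)
  cls_rank <- sm$ranking[sm$ranking$head == "class", ]
  # K+ carries no diet effect in the generator: it must rank below the
  # channels that do (glucose, cholesterol, ua)
  k_rank <- cls_rank$rank[cls_rank$channel == "k"]
  for (ch in c("glucose", "cholesterol", "ua")) {
    expect_lt(cls_rank$rank[cls_rank$channel == ch], k_rank)
  }
  # single report: summary equals that report's |phi|
  one <- rep1[rep1$window_id == rep1$window_id[1] & rep1$head == "class", ]
  sm1 <- shap_summary(one)
  expect_equal(sm1$ranking$mean_abs_phi,
               abs(one$phi)[order(-abs(one$phi))], tolerance = 1e-12)
  expect_error(shap_summary(rep1[0, ]), "empty")
})
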