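# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, builder) {
  if (!exists(key, .fixture_cache)) {
    assign(key, builder(), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# a modest cohort + windows + folds, enough signal to train on quickly
small_windows <- function() {
  memoize("small_windows", function() {
    panels <- simulate_chronic(cohort_config(n_per_group = 10, seed = 11))
    w <- make_feature_windows(panels, t_len = 20, windows_per_panel = 2,
                              seed = 3)
    f <- make_stratified_folds(w$class_label, w$degree_label, k = 5,
                               seed = 2, subject_ids = w$subject_id)
    list(panels = panels, windows = w, folds = f)
  })
}

# one trained CV on the small cohort (~15 s), reused across ML tests
small_cv <- function() {
  memoize("small_cv", function() {
    fx <- small_windows()
    train_mtl(fx$windows, fx$folds, mtl_config(epochs = 15, seed = 9))
  })
}

# a zero-effect (exchangeable-groups) cohort
null_cohort_config <- function(n_per_group = 10, seed = 5) {
  rates <- default_effect_rates()
  rates <- lapply(rates, function(r) r * 0)
  cohort_config(n_per_group = n_per_group, effect_rates = rates,
                s_max = c(CON = 0, HFFD = 0, HFFSD = 0), seed = seed)
}

# synthetic toy windows: `n` per class, `c_in` channels, T = 1, linearly
# separable along channel 1
toy_windows <- function(n = 20, sep = 4, seed = 1) {
  set.seed(seed)
  xs <- c(lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(6), 6, 1); rownames(m) <- paste0("ch", 1:6); m
  }),
  lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(6), 6, 1); m[1, 1] <- m[1, 1] + sep
    rownames(m) <- paste0("ch", 1:6); m
  }))
  tibble::tibble(
    x = xs,
    class_label = factor(rep(c("A", "B"), each = n)),
    degree_label = rep(c(0, 1), each = n) +
      stats::rnorm(2 * n, 0, 0.01),
    subject_id = sprintf("s%03d", seq_len(2 * n)),
    window_id = sprintf("w%03d", seq_len(2 * n))
  )
}

# the full-scale default experiment (~1,500 windows, default MTL config);
# trained once and shared by the headline-metric acceptance tests
acceptance_cv <- function() {
  memoize("acceptance_cv", function() {
    panels <- simulate_chronic(cohort_config(n_per_group = 25, seed = 101))
    w <- make_feature_windows(panels, seed = 102)
    f <- make_stratified_folds(w$class_label, w$degree_label, k = 5,
                               seed = 103, subject_ids = w$subject_id)
    list(windows = w, folds = f,
         cv = train_mtl(w, f, mtl_config(seed = 104)))
  })
}
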