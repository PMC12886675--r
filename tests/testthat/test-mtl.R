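test_that("analytic gradients match finite differences", {
  ns <- asNamespace("multisense")
  set.seed(42)
  t_len <- 7; b <- 4
  net <- ns$net_init(c_in = 3, conv_channels = c(4L, 5L), kernel = 3,
                     n_class = 3, cls_hidden = 6L, reg_hidden = integer())
  x <- matrix(rnorm(b * t_len * 3), b * t_len, 3)
  y_cls <- sample(3, b, replace = TRUE)
  y_deg <- rnorm(b)
  lg <- ns$net_loss_grads(net, x, y_cls, y_deg, lambda = 0.7, b, t_len)
  loss_fn <- function(nn) {
    l <- ns$net_loss_grads(nn, x, y_cls, y_deg, 0.7, b, t_len)
    l$ce + 0.7 * l$mse
  }
  gl <- list(conv = lg$grads$conv, cls = lg$grads$cls, reg = lg$grads$reg)
  eps <- 1e-6
  worst <- 0
  for (p in list(c("conv", 1), c("conv", 2), c("cls", 1), c("cls", 2),
                 c("reg", 1))) {
    blk <- p[[1]]; i <- as.integer(p[[2]])
    for (nm in c("W", "b")) {
      par <- net[[blk]][[i]][[nm]]
      g_an <- gl[[blk]][[i]][[if (nm == "W") "dW" else "db"]]
      for (j in sample(length(par), min(5, length(par)))) {
        n2 <- net
        n2[[blk]][[i]][[nm]][j] <- par[j] + eps
        f1 <- loss_fn(n2)
        n2[[blk]][[i]][[nm]][j] <- par[j] - eps
        f0 <- loss_fn(n2)
        num <- (f1 - f0) / (2 * eps)
        worst <- max(worst, abs(num - g_an[j]) /
                       max(1e-8, abs(num) + abs(g_an[j])))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("training learns the default small cohort on both tasks", {
  cv <- small_cv()
  expect_length(cv$models, 5)
  expect_gte(mean(cv$metrics$val_accuracy), 0.9)
  expect_gte(mean(cv$metrics$val_r2), 0.9)
  # loss decreases between first and last epoch on every fold
  h <- cv$history
  first <- h[h$epoch == 1, ]
  last <- h[h$epoch == max(h$epoch), ]
  expect_true(all(last$ce_loss < first$ce_loss))
  expect_true(all(last$mse_loss < first$mse_loss))
  expect_true(all(is.finite(h$ce_loss)), info = "losses finite")
  expect_equal(nrow(h), 5 * cv$config$epochs)
})

test_that("predictions form a probability simplex and are deterministic", {
  cv <- small_cv()
  fx <- small_windows()
  pr <- predict(cv$models[[1]], fx$windows[1:10, ])
  probs <- as.matrix(pr[paste0(".prob_", cv$models[[1]]$class_levels)])
  expect_equal(unname(rowSums(probs)), rep(1, 10), tolerance = 1e-6)
  expect_true(all(is.finite(pr$.pred_degree)))
  expect_true(all(pr$.pred_degree >= 0 & pr$.pred_degree <= 1))
  # duplicated input rows give identical outputs
  dup <- fx$windows[c(1, 1), ]
  pd <- predict(cv$models[[1]], dup)
  expect_identical(pd[1, ], pd[2, ])
  # wrong channel count is rejected
  bad <- tibble::tibble(x = list(matrix(0, 4, 20)))
  expect_error(predict(cv$models[[1]], bad), "channels")
})

test_that("training is reproducible given config and seed", {
  w <- toy_windows(n = 15, seed = 2)
  f <- make_stratified_folds(w$class_label, w$degree_label, k = 3,
                             seed = 1)
  cfg <- mtl_config(conv_channels = c(4L, 8L), epochs = 4, seed = 5)
  a <- train_mtl(w, f, cfg)
  b <- train_mtl(w, f, cfg)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$history$ce_loss, b$history$ce_loss)
  expect_identical(a$models[[1]]$net$conv[[1]]$W,
                   b$models[[1]]$net$conv[[1]]$W)
})

test_that("lambda = 0 removes the regression gradient but not the classifier", {
  fx <- small_windows()
  cv0 <- train_mtl(fx$windows, fx$folds,
                   mtl_config(epochs = 10, lambda = 0, seed = 9))
  expect_lte(mean(cv0$metrics$val_r2), 0.1)
  expect_gte(mean(cv0$metrics$val_accuracy), 0.85)
})

test_that("permuted labels drop accuracy to chance", {
  fx <- small_windows()
  w <- fx$windows
  set.seed(31)
  w$class_label <- sample(w$class_label)
  f <- make_stratified_folds(w$class_label, w$degree_label, k = 5,
                             seed = 2)
  cv <- train_mtl(w, f, mtl_config(epochs = 8, seed = 9))
  expect_gte(mean(cv$metrics$val_accuracy), 0.33 - 0.1)
  expect_lte(mean(cv$metrics$val_accuracy), 0.33 + 0.1)
})

test_that("embeddings have the configured width and separate classes", {
  cv <- small_cv()
  fx <- small_windows()
  emb <- embed_windows(cv$models[[1]], fx$windows[1:20, ])
  expect_equal(dim(emb), c(20, tail(cv$config$conv_channels, 1)))
  expect_identical(embed_windows(cv$models[[1]], fx$windows[c(3, 3), ])[1, ],
                   embed_windows(cv$models[[1]], fx$windows[c(3, 3), ])[2, ])
  expect_error(embed_windows(list(), fx$windows[1:5, ]), "trained")
})

test_that("learned embeddings separate groups better than raw features", {
  cv <- small_cv()
  fx <- small_windows()
  w_all <- fx$windows
  emb <- embed_windows(cv$models[[1]], w_all)
  # raw = the full standardized time-series windows the network consumes
  raw <- scale(t(vapply(w_all$x, as.vector,
                        numeric(length(w_all$x[[1]])))))
  s_emb <- tsne_separability(emb, w_all$class_label, seed = 4,
                             perplexity = 30, max_iter = 400)$silhouette
  s_raw <- tsne_separability(raw, w_all$class_label, seed = 4,
                             perplexity = 30, max_iter = 400)$silhouette
  expect_gt(s_emb, s_raw)
})

test_that("chance-band accuracy holds on the exchangeable cohort", {
  panels <- simulate_chronic(null_cohort_config(n_per_group = 10, seed = 23))
  w <- make_feature_windows(panels, t_len = 20, windows_per_panel = 2,
                            seed = 6)
  f <- make_stratified_folds(w$class_label, w$degree_label, k = 5,
                             seed = 3, subject_ids = w$subject_id)
  cv <- train_mtl(w, f, mtl_config(epochs = 8, seed = 17))
  acc <- mean(cv$metrics$val_accuracy)
  expect_gte(acc, 0.2)
  expect_lte(acc, 0.47)
})
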