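#' Flatten feature windows to per-sample feature vectors
#'
#' Collapses each 6 x T window to its per-channel time means — the
#' steady-state 6-vector representation used by the classical baselines.
#'
#' @param windows feature-window tibble.
#' @return tibble of six numeric feature columns (named by channel) plus
#'   `class_label` and `degree_label`.
#' @export
flatten_windows <- function(windows) {
  feats <- t(vapply(windows$x, rowMeans,
                    numeric(nrow(windows$x[[1]]))))
  colnames(feats) <- rownames(windows$x[[1]]) %||%
    paste0("ch", seq_len(ncol(feats)))
  out <- tibble::as_tibble(as.data.frame(feats))
  out$class_label <- windows$class_label
  out$degree_label <- windows$degree_label
  out
}

#' Classical machine-learning baselines under the same folds
#'
#' Comparison harness: K-nearest neighbours, support-vector machine,
#' decision tree, random forest and gradient-boosted trees (XGBoost), each
#' trained per fold on the flattened (per-channel mean) features
#' standardized with training statistics only, under the identical fold
#' assignment as the CNN. Classification accuracy is reported for all
#' models; degree R-squared for those with a regression mode (KNN has
#' none here).
#'
#' @param windows feature-window tibble.
#' @param folds `fold_assignment` shared with the CNN run.
#' @param seed integer seed for the stochastic learners.
#' @return a tibble `model, fold, val_accuracy, val_r2` plus a
#'   `fold-mean` summary attribute `summary` (tibble
#'   `model, mean_accuracy, mean_r2`).
#' @export
train_baselines <- function(windows, folds, seed = 1L) {
  stopifnot(inherits(folds, "fold_assignment"))
  flat <- flatten_windows(windows)
  feat_cols <- setdiff(names(flat), c("class_label", "degree_label"))
  rows <- list()
  for (f in seq_len(folds$k)) {
    tr <- flat[folds$assignments != f, ]
    va <- flat[folds$assignments == f, ]
    z <- zscore_fit_transform(tr[feat_cols], va[feat_cols])
    x_tr <- as.matrix(z$train); x_va <- as.matrix(z$apply_to)
    y_tr <- droplevels(tr$class_label); y_va <- va$class_label
    d_tr <- tr$degree_label; d_va <- va$degree_label
    for (mod in c("KNN", "SVM", "DT", "RF", "XGBoost")) {
      res <- tryCatch(
        fit_one_baseline(mod, x_tr, y_tr, d_tr, x_va, seed + f),
        error = function(e) {
          stop("baseline `", mod, "` failed on fold ", f, ": ",
               conditionMessage(e), call. = FALSE)
        })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = mod, fold = f,
        val_accuracy = mean(as.character(res$class) ==
                              as.character(y_va)),
        val_r2 = if (is.null(res$degree)) NA_real_ else
          r_squared(d_va, res$degree)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- out |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_accuracy = mean(.data$val_accuracy),
                     mean_r2 = mean(.data$val_r2), .groups = "drop")
  out
}

fit_one_baseline <- function(model, x_tr, y_tr, d_tr, x_va, seed) {
  df_tr <- data.frame(x_tr); df_va <- data.frame(x_va)
  switch(model,
    KNN = with_seed(seed, {
      cls <- class::knn(x_tr, x_va, cl = y_tr, k = 5)
      list(class = cls, degree = NULL)
    }),
    SVM = {
      fit_c <- e1071::svm(x_tr, y_tr, kernel = "radial")
      fit_r <- e1071::svm(x_tr, d_tr, kernel = "radial")
      list(class = predict(fit_c, x_va),
           degree = as.numeric(predict(fit_r, x_va)))
    },
    DT = {
      df_tr$.y <- y_tr
      fit_c <- rpart::rpart(.y ~ ., df_tr, method = "class")
      df_tr$.y <- d_tr
      fit_r <- rpart::rpart(.y ~ ., df_tr, method = "anova")
      list(class = predict(fit_c, df_va, type = "class"),
           degree = as.numeric(predict(fit_r, df_va)))
    },
    RF = with_seed(seed, {
      fit_c <- randomForest::randomForest(x_tr, y_tr, ntree = 200)
      fit_r <- randomForest::randomForest(x_tr, d_tr, ntree = 200)
      list(class = predict(fit_c, x_va),
           degree = as.numeric(predict(fit_r, x_va)))
    }),
    XGBoost = with_seed(seed, {
      dtr_c <- xgboost::xgb.DMatrix(x_tr, label = as.integer(y_tr) - 1L)
      fit_c <- xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y_tr), nthread = 1),
        data = dtr_c, nrounds = 50, verbose = 0
      )
      dtr_r <- xgboost::xgb.DMatrix(x_tr, label = d_tr)
      fit_r <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", nthread = 1),
        data = dtr_r, nrounds = 50, verbose = 0
      )
      dva <- xgboost::xgb.DMatrix(x_va)
      prob <- matrix(predict(fit_c, dva), ncol = nlevels(y_tr),
                     byrow = TRUE)
      list(class = factor(levels(y_tr)[max.col(prob)],
                          levels = levels(y_tr)),
           degree = as.numeric(predict(fit_r, dva)))
    })
  )
}
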