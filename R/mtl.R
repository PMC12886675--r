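#' Multi-task CNN configuration
#'
#' Architecture and optimisation settings of the multi-task 1-D CNN: a
#' hard-shared block of five convolutional layers over the 6-channel time
#' window, global average pooling, and two task-specific branches — a
#' 3-way classification head and a scalar regression head — trained
#' jointly with cross-entropy plus `lambda` times MSE.
#'
#' @param conv_channels output channels of the shared conv layers
#'   (default `c(16, 32, 32, 64, 64)`, i.e. five layers).
#' @param kernel odd convolution kernel width (default 3, stride 1, ReLU,
#'   "same" padding).
#' @param cls_hidden,reg_hidden integer vectors of hidden widths for the
#'   task branches; empty (the default) means a single linear layer from
#'   the pooled features.
#' @param lambda weight of the regression MSE in the joint loss.
#' @param weight_decay decoupled L2 weight decay applied at each Adam step
#'   (AdamW); regularises the shared block so the class boundary tracks
#'   the population rather than the training draw.
#' @param label_smoothing fraction of the one-hot class target spread
#'   uniformly over classes; keeps the cross-entropy gradient alive after
#'   the training set is fitted.
#' @param augment_offset_sd SD (in standardized signal units) of a random
#'   per-channel DC offset added to each training window, constant over
#'   time — augmentation that emulates subject- and sensor-level baseline
#'   variability so the learned boundary is invariant to it. 0 disables.
#' @param lr initial Adam learning rate.
#' @param lr_schedule `"cosine"` (default) anneals the learning rate per
#'   epoch with a cosine decay to 5% of `lr`, which settles the decision
#'   boundary in late training; `"constant"` keeps `lr` fixed.
#' @param epochs training epochs (default 80).
#' @param batch_size minibatch size.
#' @param seed integer seed governing initialisation and batching.
#' @return an object of class `mtl_config`.
#' @export
mtl_config <- function(conv_channels = c(16L, 32L, 32L, 64L, 64L),
                       kernel = 3L,
                       cls_hidden = integer(),
                       reg_hidden = integer(),
                       lambda = 1,
                       weight_decay = 1e-4,
                       label_smoothing = 0.1,
                       augment_offset_sd = 0.1,
                       lr = 1e-3,
                       lr_schedule = c("cosine", "constant"),
                       epochs = 80L,
                       batch_size = 32L,
                       seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(kernel %% 2L == 1L, lambda >= 0, lr > 0, epochs >= 1,
            batch_size >= 1, weight_decay >= 0, augment_offset_sd >= 0,
            label_smoothing >= 0, label_smoothing < 1)
  structure(
    list(conv_channels = as.integer(conv_channels),
         kernel = as.integer(kernel),
         cls_hidden = as.integer(cls_hidden),
         reg_hidden = as.integer(reg_hidden),
         lambda = lambda, weight_decay = weight_decay,
         label_smoothing = label_smoothing,
         augment_offset_sd = augment_offset_sd,
         lr = lr, lr_schedule = lr_schedule,
         epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "mtl_config"
  )
}

#' Train the multi-task CNN under cross-validation
#'
#' Trains one model per fold of `folds`. For each fold, channel-wise
#' Z-score statistics and the degree-label scaling are fitted on the
#' training windows only and applied to the validation windows; the model
#' then minimises `cross-entropy + lambda * MSE` with Adam. Per-fold
#' validation accuracy and degree R-squared are reported together with the
#' per-epoch loss history.
#'
#' @param windows feature-window tibble from [make_feature_windows()]
#'   (list-column `x`, `class_label`, `degree_label`).
#' @param folds a `fold_assignment` from [make_stratified_folds()].
#' @param config an [mtl_config()].
#' @return an object of class `mtl_cv`: list with `models` (one
#'   `mtl_model` per fold), `metrics` (per-fold tibble
#'   `fold, val_accuracy, val_r2`), `history` (tibble
#'   `epoch, fold, ce_loss, mse_loss, val_acc, val_r2`) and `config`.
#' @export
train_mtl <- function(windows, folds, config = mtl_config()) {
  stopifnot(inherits(folds, "fold_assignment"))
  n <- nrow(windows)
  stopifnot(length(folds$assignments) == n)
  t_len <- ncol(windows$x[[1]])
  levels_cls <- levels(windows$class_label)

  models <- vector("list", folds$k)
  history <- list()
  metrics <- list()
  for (f in seq_len(folds$k)) {
    tr_idx <- which(folds$assignments != f)
    va_idx <- which(folds$assignments == f)
    fit <- train_mtl_fold(windows, tr_idx, va_idx, config, t_len,
                          levels_cls, fold = f)
    models[[f]] <- fit$model
    history[[f]] <- fit$history
    metrics[[f]] <- tibble::tibble(fold = f,
                                   val_accuracy = fit$val_accuracy,
                                   val_r2 = fit$val_r2)
  }
  structure(
    list(models = models, metrics = dplyr::bind_rows(metrics),
         history = dplyr::bind_rows(history), config = config,
         folds = folds),
    class = "mtl_cv"
  )
}

train_mtl_fold <- function(windows, tr_idx, va_idx, config, t_len,
                           levels_cls, fold) {
  scaler <- fit_window_scaler(windows$x[tr_idx])
  x_tr <- stack_windows(apply_window_scaler(windows$x[tr_idx], scaler))
  y_cls_tr <- as.integer(windows$class_label[tr_idx])
  deg_mu <- mean(windows$degree_label[tr_idx])
  deg_sd <- stats::sd(windows$degree_label[tr_idx])
  if (!is.finite(deg_sd) || deg_sd == 0) deg_sd <- 1
  y_deg_tr <- (windows$degree_label[tr_idx] - deg_mu) / deg_sd

  has_val <- length(va_idx) > 0
  if (has_val) {
    x_va <- stack_windows(apply_window_scaler(windows$x[va_idx], scaler))
    y_cls_va <- as.integer(windows$class_label[va_idx])
    y_deg_va <- windows$degree_label[va_idx]
  }

  n_tr <- length(tr_idx)
  with_seed(child_seed(config$seed, fold), {
    net <- net_init(c_in = nrow(windows$x[[1]]),
                    conv_channels = config$conv_channels,
                    kernel = config$kernel, n_class = length(levels_cls),
                    cls_hidden = config$cls_hidden,
                    reg_hidden = config$reg_hidden)
    state <- adam_init(net)
    t_step <- 0L
    hist <- vector("list", config$epochs)
    for (ep in seq_len(config$epochs)) {
      lr_ep <- if (identical(config$lr_schedule, "constant")) config$lr else
        config$lr * (0.05 + 0.95 * 0.5 *
                       (1 + cos(pi * (ep - 1) / max(1, config$epochs - 1))))
      ord <- sample(n_tr)
      ce_sum <- 0; mse_sum <- 0; nb <- 0L
      i <- 1L
      while (i <= n_tr) {
        bs <- ord[i:min(i + config$batch_size - 1L, n_tr)]
        rows <- rep((bs - 1L) * t_len, each = t_len) + seq_len(t_len)
        xb <- x_tr[rows, , drop = FALSE]
        if (config$augment_offset_sd > 0) {
          off <- matrix(rnorm(length(bs) * ncol(xb), 0,
                              config$augment_offset_sd),
                        length(bs), ncol(xb))
          xb <- xb + off[rep(seq_along(bs), each = t_len), , drop = FALSE]
        }
        lg <- tryCatch(
          net_loss_grads(net, xb, y_cls_tr[bs],
                         y_deg_tr[bs], config$lambda, length(bs), t_len,
                         label_smoothing = config$label_smoothing),
          error = function(e) {
            stop("training aborted at epoch ", ep, " (lr = ", config$lr,
                 "): ", conditionMessage(e), call. = FALSE)
          })
        t_step <- t_step + 1L
        up <- adam_step(net, lg$grads, state, lr_ep, t_step,
                        weight_decay = config$weight_decay)
        net <- up$net; state <- up$state
        ce_sum <- ce_sum + lg$ce; mse_sum <- mse_sum + lg$mse
        nb <- nb + 1L
        i <- i + config$batch_size
      }
      val_acc <- NA_real_; val_r2 <- NA_real_
      if (has_val) {
        pv <- net_predict_mat(net, x_va, length(va_idx), t_len)
        val_acc <- mean(max.col(pv$logits) == y_cls_va)
        deg_hat <- pmin(pmax(pv$reg * deg_sd + deg_mu, 0), 1)
        val_r2 <- r_squared(y_deg_va, deg_hat)
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, fold = fold,
                                   ce_loss = ce_sum / nb,
                                   mse_loss = mse_sum / nb,
                                   val_acc = val_acc, val_r2 = val_r2)
    }
    model <- structure(
      list(net = net, scaler = scaler, degree_mean = deg_mu,
           degree_sd = deg_sd, t_len = t_len, class_levels = levels_cls,
           config = config, fold = fold),
      class = "mtl_model"
    )
    last <- hist[[config$epochs]]
    list(model = model, history = dplyr::bind_rows(hist),
         val_accuracy = last$val_acc, val_r2 = last$val_r2)
  })
}

r_squared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

windows_x_list <- function(windows) {
  if (is.data.frame(windows)) windows$x else windows
}

#' Predict class probabilities and health degree
#'
#' Standardizes the input windows with the model's stored training
#' statistics, runs the shared block and both heads, and returns softmax
#' class probabilities (summing to 1), the argmax class, the raw degree
#' output and the degree clipped to [0, 1] for reporting.
#'
#' @param object an `mtl_model` (one fold of [train_mtl()]).
#' @param windows a feature-window tibble or a list of 6 x T matrices.
#' @param ... unused.
#' @return a tibble with `.pred_class`, one `.prob_<level>` column per
#'   class, `.pred_degree` (clipped) and `.pred_degree_raw`.
#' @export
predict.mtl_model <- function(object, windows, ...) {
  xs <- windows_x_list(windows)
  if (nrow(xs[[1]]) != length(object$scaler$mean)) {
    stop("windows must have ", length(object$scaler$mean), " channels",
         call. = FALSE)
  }
  xmat <- stack_windows(apply_window_scaler(xs, object$scaler))
  pv <- net_predict_mat(object$net, xmat, length(xs), object$t_len)
  lg <- pv$logits - apply(pv$logits, 1, max)
  p <- exp(lg) / rowSums(exp(lg))
  colnames(p) <- paste0(".prob_", object$class_levels)
  deg_raw <- pv$reg * object$degree_sd + object$degree_mean
  out <- tibble::as_tibble(as.data.frame(p))
  out$.pred_class <- factor(object$class_levels[max.col(pv$logits)],
                            levels = object$class_levels)
  out$.pred_degree <- pmin(pmax(deg_raw, 0), 1)
  out$.pred_degree_raw <- deg_raw
  out
}

#' Shared-block embeddings
#'
#' Returns the pooled penultimate shared-feature vectors (the global
#' average over time of the last conv layer) for a set of windows — the
#' learned representation whose cluster structure the t-SNE analysis
#' inspects.
#'
#' @param model an `mtl_model`.
#' @param windows a feature-window tibble or list of matrices.
#' @return numeric matrix, one row per window, width = last shared-layer
#'   channels.
#' @export
embed_windows <- function(model, windows) {
  if (!inherits(model, "mtl_model")) {
    stop("`model` must be a trained `mtl_model`", call. = FALSE)
  }
  xs <- windows_x_list(windows)
  xmat <- stack_windows(apply_window_scaler(xs, model$scaler))
  net_predict_mat(model$net, xmat, length(xs), model$t_len)$gap
}

#' @export
print.mtl_cv <- function(x, ...) {
  cat("<mtl_cv> ", x$folds$k, "-fold cross-validated multi-task CNN\n",
      sep = "")
  cat(sprintf("  fold-mean accuracy %.4f, fold-mean R^2 %.4f\n",
              mean(x$metrics$val_accuracy), mean(x$metrics$val_r2)))
  invisible(x)
}

#' @method tidy mtl_cv
#' @export
tidy.mtl_cv <- function(x, ...) x$metrics

#' @method glance mtl_cv
#' @export
glance.mtl_cv <- function(x, ...) {
  tibble::tibble(
    k = x$folds$k,
    mean_accuracy = mean(x$metrics$val_accuracy),
    mean_r2 = mean(x$metrics$val_r2),
    epochs = x$config$epochs,
    lambda = x$config$lambda
  )
}

#' Training-curve plot
#'
#' Per-fold cross-entropy and MSE training curves, the learning diagnostic
#' of the joint optimisation.
#'
#' @param object an `mtl_cv`.
#' @param ... unused.
#' @method autoplot mtl_cv
#' @export
autoplot.mtl_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("ce_loss", "mse_loss"),
                            names_to = "loss", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = factor(.data$fold))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::labs(colour = "fold", y = "training loss") +
    ggplot2::theme_minimal()
}
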