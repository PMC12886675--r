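#' Multiclass classification metrics
#'
#' Accuracy, macro precision/recall/F1 and the confusion matrix from class
#' probabilities. Macro metrics average per-class values with the 0/0 -> 0
#' convention (a class never predicted contributes precision 0).
#'
#' @param y_true true labels: a factor, or integers in `0:(K-1)`.
#' @param probabilities n x K matrix of class probabilities, rows summing
#'   to 1; column order follows the factor levels (or class index).
#' @param levels optional class names for integer labels.
#' @return list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1` and `confusion` (K x K matrix, true classes in rows).
#' @examples
#' p <- diag(3)[c(1, 2, 2), ]
#' classification_metrics(factor(c("a", "b", "c")), p)$accuracy
#' @export
classification_metrics <- function(y_true, probabilities, levels = NULL) {
  k <- ncol(probabilities)
  if (is.factor(y_true)) {
    levels <- levels %||% levels(y_true)
    y <- as.integer(y_true)
  } else {
    if (any(!y_true %in% 0:(k - 1))) {
      stop("integer labels must lie in 0..", k - 1, call. = FALSE)
    }
    levels <- levels %||% as.character(0:(k - 1))
    y <- as.integer(y_true) + 1L
  }
  if (any(abs(rowSums(probabilities) - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  pred <- max.col(probabilities)
  confusion <- matrix(0L, k, k, dimnames = list(true = levels,
                                                pred = levels))
  for (i in seq_along(y)) {
    confusion[y[i], pred[i]] <- confusion[y[i], pred[i]] + 1L
  }
  per_class <- vapply(seq_len(k), function(c) {
    tp <- confusion[c, c]
    prec <- if (sum(confusion[, c]) == 0) 0 else tp / sum(confusion[, c])
    rec <- if (sum(confusion[c, ]) == 0) 0 else tp / sum(confusion[c, ])
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }, numeric(3))
  list(
    accuracy = sum(diag(confusion)) / length(y),
    macro_precision = mean(per_class[1, ]),
    macro_recall = mean(per_class[2, ]),
    macro_f1 = mean(per_class[3, ]),
    confusion = confusion
  )
}

#' One-vs-rest precision-recall curves
#'
#' For each class, sweeps the class-probability threshold over every
#' distinct score, pooling tied scores into a single PR point, and computes
#' the average precision as the step integral
#' `sum (recall_i - recall_{i-1}) * precision_i`.
#'
#' @inheritParams classification_metrics
#' @return a tibble `class, threshold, precision, recall` with attribute
#'   `average_precision` (named vector per class). Classes absent from
#'   `y_true` are skipped with a warning.
#' @export
pr_curves <- function(y_true, probabilities, levels = NULL) {
  k <- ncol(probabilities)
  if (is.factor(y_true)) {
    levels <- levels %||% levels(y_true)
    y <- as.integer(y_true)
  } else {
    levels <- levels %||% as.character(0:(k - 1))
    y <- as.integer(y_true) + 1L
  }
  out <- list(); ap <- stats::setNames(numeric(0), character(0))
  for (c in seq_len(k)) {
    pos <- y == c
    if (!any(pos)) {
      warning("class `", levels[c], "` absent from y_true; skipped",
              call. = FALSE)
      next
    }
    sc <- probabilities[, c]
    thr <- sort(unique(sc), decreasing = TRUE)
    prec <- rec <- numeric(length(thr))
    for (i in seq_along(thr)) {
      sel <- sc >= thr[i]
      prec[i] <- sum(pos & sel) / sum(sel)
      rec[i] <- sum(pos & sel) / sum(pos)
    }
    ap_c <- sum(diff(c(0, rec)) * prec)
    out[[length(out) + 1L]] <- tibble::tibble(
      class = levels[c], threshold = thr, precision = prec, recall = rec
    )
    ap[levels[c]] <- ap_c
  }
  res <- dplyr::bind_rows(out)
  attr(res, "average_precision") <- ap
  res
}

#' Regression metrics
#'
#' `R^2 = 1 - SS_res / SS_tot`, root-mean-square error and mean absolute
#' error.
#'
#' @param y_true numeric truth, n >= 2 with nonzero variance.
#' @param y_pred numeric predictions.
#' @return list with `r2`, `rmse`, `mae`.
#' @examples
#' regression_metrics(c(0, 1, 2), c(0, 1, 1))$r2  # 0.5
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 2L) stop("need n >= 2", call. = FALSE)
  if (var(y_true) == 0) {
    stop("zero-variance truth; R^2 undefined", call. = FALSE)
  }
  list(
    r2 = r_squared(y_true, y_pred),
    rmse = sqrt(mean((y_true - y_pred)^2)),
    mae = mean(abs(y_true - y_pred))
  )
}

#' PR-curve plot
#'
#' @param pr result of [pr_curves()].
#' @return a ggplot.
#' @export
plot_pr_curves <- function(pr) {
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$class)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
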