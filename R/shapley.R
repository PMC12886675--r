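#' Exact Shapley attribution over sensor channels
#'
#' Treats each of the six channels as one player: a coalition includes or
#' excludes all time samples of a channel, with excluded channels replaced
#' by the baseline. With 6 channels the 2^6 = 64 coalitions are enumerated
#' exactly with the standard combinatorial weights
#' `|S|! (n - |S| - 1)! / n!`, so the attribution satisfies the Shapley
#' axioms by construction; in particular efficiency:
#' `sum(phi) = f(x) - f(baseline)`.
#'
#' @param predict_fn function taking a channels x T matrix and returning a
#'   finite scalar model output (a class logit or the degree output).
#' @param x input window, channels x T matrix (a plain vector is treated
#'   as T = 1).
#' @param baseline reference window of the same shape (conventionally the
#'   channel-wise training means — the zero matrix after standardization).
#' @return named numeric vector of Shapley values, one per channel, with
#'   attributes `f_x` and `f_baseline`.
#' @examples
#' f <- function(m) 2 * m[1, 1] + 3 * m[2, 1]
#' exact_shapley(f, c(1, 1, 0, 0, 0, 0), numeric(6))
#' @export
exact_shapley <- function(predict_fn, x, baseline) {
  x <- as_window_matrix(x)
  baseline <- as_window_matrix(baseline)
  stopifnot(identical(dim(x), dim(baseline)))
  n <- nrow(x)
  masks <- 0:(2^n - 1)
  v <- vapply(masks, function(m) {
    inc <- bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) > 0L
    xm <- baseline
    xm[inc, ] <- x[inc, , drop = FALSE]
    val <- predict_fn(xm)
    if (!is.finite(val)) {
      stop("predict_fn returned a non-finite value for coalition mask ",
           paste(as.integer(inc), collapse = ""), call. = FALSE)
    }
    val
  }, numeric(1))
  # weights over coalition sizes |S| of N \ {i}
  wt <- factorial(0:(n - 1)) * factorial(n - 1 - 0:(n - 1)) / factorial(n)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m,
    bitwShiftL(1L, 0:(n - 1L))) > 0L), integer(1))
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- sizes[bitwAnd(masks, bit) == 0L]
    phi[i] <- sum(wt[s + 1L] *
                    (v[match(bitwOr(without, bit), masks)] -
                       v[match(without, masks)]))
  }
  names(phi) <- rownames(x) %||% paste0("ch", seq_len(n))
  attr(phi, "f_x") <- v[length(v)]
  attr(phi, "f_baseline") <- v[1]
  phi
}

as_window_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1)
}

# all permutations of 1..n (n small), rows = permutations
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Sampled (permutation) Shapley attribution
#'
#' Unbiased permutation estimator of the Shapley values: channels are added
#' in random order and each channel is credited with its marginal change in
#' the model output; the estimate is the mean marginal contribution over
#' permutations, with a standard error from the permutation variance. With
#' `dedup = TRUE` and `n_permutations >= n!` every distinct permutation is
#' evaluated exactly once and the estimate equals [exact_shapley()].
#'
#' @inheritParams exact_shapley
#' @param n_permutations number of sampled permutations (>= 10 unless
#'   `dedup`).
#' @param seed integer seed.
#' @param dedup enumerate all `n!` distinct permutations once instead of
#'   sampling.
#' @return tibble `channel, phi, se`.
#' @export
sampled_shapley <- function(predict_fn, x, baseline, n_permutations = 100,
                            seed = 1L, dedup = FALSE) {
  x <- as_window_matrix(x)
  baseline <- as_window_matrix(baseline)
  n <- nrow(x)
  if (dedup) {
    perms <- all_permutations(n)
    if (n_permutations < nrow(perms)) {
      stop("`dedup = TRUE` needs n_permutations >= n! = ", nrow(perms),
           call. = FALSE)
    }
  } else {
    if (n_permutations < 10) {
      stop("`n_permutations` must be at least 10", call. = FALSE)
    }
    perms <- with_seed(seed, t(replicate(n_permutations, sample(n))))
  }
  contrib <- matrix(0, nrow(perms), n)
  for (r in seq_len(nrow(perms))) {
    xm <- baseline
    prev <- predict_fn(xm)
    if (!is.finite(prev)) {
      stop("predict_fn returned a non-finite value at the baseline",
           call. = FALSE)
    }
    for (ch in perms[r, ]) {
      xm[ch, ] <- x[ch, ]
      cur <- predict_fn(xm)
      if (!is.finite(cur)) {
        stop("predict_fn returned a non-finite value for a coalition ",
             "including channel ", ch, call. = FALSE)
      }
      contrib[r, ch] <- cur - prev
      prev <- cur
    }
  }
  tibble::tibble(
    channel = rownames(x) %||% paste0("ch", seq_len(n)),
    phi = colMeans(contrib),
    se = apply(contrib, 2, stats::sd) / sqrt(nrow(perms))
  )
}

#' Channel attributions of a trained multi-task model
#'
#' Computes exact Shapley values for each window on both heads: the
#' classification head is attributed on the logit of the window's
#' predicted class (not the probability, avoiding softmax coupling); the
#' regression head on the raw degree output. The baseline is the
#' channel-wise training mean held constant over time — the zero window
#' after standardization.
#'
#' @param model an `mtl_model`.
#' @param windows feature-window tibble.
#' @param max_windows cap on the number of attributed windows (attribution
#'   evaluates 64 coalitions per window and head).
#' @param seed seed for the subsample when `nrow(windows) > max_windows`.
#' @return tibble `window_id, pred_class, head, channel, phi`, with
#'   efficiency columns `f_x, f_baseline`; one row per window, head and
#'   channel.
#' @export
shap_report <- function(model, windows, max_windows = 200, seed = 1L) {
  stopifnot(inherits(model, "mtl_model"))
  n <- nrow(windows)
  keep <- if (n > max_windows) {
    with_seed(seed, sort(sample(n, max_windows)))
  } else seq_len(n)
  chans <- rownames(windows$x[[1]]) %||%
    paste0("ch", seq_len(nrow(windows$x[[1]])))
  baseline_raw <- matrix(model$scaler$mean, nrow = length(chans),
                         ncol = model$t_len)
  rownames(baseline_raw) <- chans

  one_forward <- function(m) {
    xm <- stack_windows(apply_window_scaler(list(m), model$scaler))
    net_predict_mat(model$net, xm, 1L, model$t_len)
  }
  rows <- list()
  for (i in keep) {
    x <- windows$x[[i]]
    pred <- one_forward(x)
    cls <- which.max(pred$logits[1, ])
    f_cls <- function(m) one_forward(m)$logits[1, cls]
    f_deg <- function(m) {
      one_forward(m)$reg[1] * model$degree_sd + model$degree_mean
    }
    for (head in c("class", "degree")) {
      fn <- if (head == "class") f_cls else f_deg
      phi <- exact_shapley(fn, x, baseline_raw)
      fx <- attr(phi, "f_x")
      fb <- attr(phi, "f_baseline")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        window_id = windows$window_id[i] %||% as.character(i),
        pred_class = model$class_levels[cls],
        head = head, channel = chans, phi = as.numeric(phi),
        f_x = fx, f_baseline = fb
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarise Shapley reports
#'
#' Mean absolute Shapley value per channel and head (the global importance
#' ranking) and the per-predicted-class mean signed value (the sign
#' profile showing which channels push toward each class).
#'
#' @param report tibble from [shap_report()] (or several, row-bound).
#' @return list with `ranking` (tibble
#'   `head, channel, mean_abs_phi, rank`) and `sign_profile` (tibble
#'   `pred_class, channel, mean_phi`, classification head only).
#' @export
shap_summary <- function(report) {
  if (!nrow(report)) stop("empty attribution report", call. = FALSE)
  ranking <- report |>
    dplyr::group_by(.data$head, .data$channel) |>
    dplyr::summarise(mean_abs_phi = mean(abs(.data$phi)),
                     .groups = "drop_last") |>
    dplyr::mutate(rank = rank(-.data$mean_abs_phi,
                              ties.method = "first")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$head, .data$rank)
  sign_profile <- report |>
    dplyr::filter(.data$head == "class") |>
    dplyr::group_by(.data$pred_class, .data$channel) |>
    dplyr::summarise(mean_phi = mean(.data$phi), .groups = "drop")
  list(ranking = ranking, sign_profile = sign_profile)
}

#' Shapley importance plot
#'
#' @param summary result of [shap_summary()].
#' @return a ggplot of mean |phi| per channel, facetted by head.
#' @export
plot_shap_summary <- function(summary) {
  ggplot2::ggplot(summary$ranking,
                  ggplot2::aes(x = stats::reorder(.data$channel,
                                                  .data$mean_abs_phi),
                               y = .data$mean_abs_phi)) +
    ggplot2::geom_col(fill = "#7570b3") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~head, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "mean |phi|") +
    ggplot2::theme_minimal()
}
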