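#' Z-score standardization fitted on the training split only
#'
#' Scales each feature to mean 0 and SD 1 using statistics computed on
#' `train` alone (population SD, ddof = 0); `apply_to` is transformed with
#' the training statistics, never its own, which is what keeps validation
#' data out of the preprocessing.
#'
#' @param train data frame of numeric features.
#' @param apply_to optional second data frame with the same columns.
#' @return list with `train` (standardized tibble), `apply_to`
#'   (standardized with train statistics, or `NULL`), and `stats` (tibble
#'   `feature, mean, sd`, tagged with `fit_on = "train"`).
#' @examples
#' zscore_fit_transform(data.frame(x = c(1, 2, 3)))$train$x
#' @export
zscore_fit_transform <- function(train, apply_to = NULL) {
  num <- vapply(train, is.numeric, logical(1))
  feats <- names(train)[num]
  mu <- vapply(train[feats], mean, numeric(1))
  sdev <- vapply(train[feats], function(v) {
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  if (any(sdev == 0)) {
    stop("constant feature(s) in train: ",
         paste(feats[sdev == 0], collapse = ", "), call. = FALSE)
  }
  scale_df <- function(df) {
    out <- df
    for (f in feats) out[[f]] <- (df[[f]] - mu[[f]]) / sdev[[f]]
    tibble::as_tibble(out)
  }
  stats_tbl <- tibble::tibble(feature = feats, mean = unname(mu),
                              sd = unname(sdev))
  attr(stats_tbl, "fit_on") <- "train"
  list(
    train = scale_df(train),
    apply_to = if (!is.null(apply_to)) scale_df(apply_to),
    stats = stats_tbl
  )
}

#' Stratified k-fold assignment balancing class and degree
#'
#' Splits samples into `k` folds so that (a) per-fold class counts are
#' within one sample of the global proportions and (b) the degree
#' distribution is balanced across folds: within each class, samples are
#' ordered by degree and dealt to folds in consecutive blocks of `k`, with
#' a seeded random fold order inside every block. When `subject_ids` is
#' supplied the dealt unit is the subject (ordered by its mean degree), so
#' no subject's samples are split between training and validation.
#'
#' @param class_labels vector of class labels.
#' @param degree_labels numeric degree labels, same length.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param subject_ids optional subject identifiers; each subject must carry
#'   a single class.
#' @return an object of class `fold_assignment`: list with `k`,
#'   `assignments` (integer fold 1..k per sample) and
#'   `stratification_report` (per-fold class counts and degree-quantile
#'   counts).
#' @export
make_stratified_folds <- function(class_labels, degree_labels, k = 5L,
                                  seed = 1L, subject_ids = NULL) {
  n <- length(class_labels)
  stopifnot(length(degree_labels) == n)
  class_labels <- as.character(class_labels)

  if (is.null(subject_ids)) {
    units <- tibble::tibble(id = seq_len(n), class = class_labels,
                            degree = degree_labels)
    sample_unit <- units$id
  } else {
    stopifnot(length(subject_ids) == n)
    cls_per_subj <- tapply(class_labels, subject_ids,
                           function(v) length(unique(v)))
    if (any(cls_per_subj > 1)) {
      stop("each subject must belong to a single class", call. = FALSE)
    }
    units <- tibble::tibble(
      id = unique(subject_ids),
      class = class_labels[match(unique(subject_ids), subject_ids)],
      degree = as.numeric(tapply(degree_labels, subject_ids, mean)[
        unique(subject_ids)])
    )
    sample_unit <- subject_ids
  }

  counts <- table(units$class)
  if (any(counts < k)) {
    small <- names(counts)[counts < k]
    stop("class(es) with fewer units than k = ", k, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  }

  unit_fold <- stats::setNames(integer(nrow(units)), units$id)
  with_seed(seed, {
    for (cl in sort(unique(units$class))) {
      sub <- units[units$class == cl, ]
      # seeded jitter breaks degree ties before sorting
      ord <- order(sub$degree, runif(nrow(sub)))
      ids <- sub$id[ord]
      folds <- integer(length(ids))
      i <- 1L
      while (i <= length(ids)) {
        block <- i:min(i + k - 1L, length(ids))
        folds[block] <- sample(k)[seq_along(block)]
        i <- i + k
      }
      unit_fold[as.character(ids)] <- folds
    }
  })
  assignments <- unname(unit_fold[as.character(sample_unit)])

  qs <- cut(degree_labels,
            breaks = unique(quantile(degree_labels,
                                     probs = seq(0, 1, 0.25))),
            include.lowest = TRUE)
  report <- tibble::tibble(
    fold = assignments, class = class_labels,
    degree_quartile = as.character(qs)
  ) |>
    dplyr::count(.data$fold, .data$class, .data$degree_quartile)

  structure(
    list(k = as.integer(k), assignments = assignments,
         stratification_report = report),
    class = "fold_assignment"
  )
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("<fold_assignment> k =", x$k, "over", length(x$assignments),
      "samples\n")
  print(table(fold = x$assignments))
  invisible(x)
}

#' @method tidy fold_assignment
#' @export
tidy.fold_assignment <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$assignments), fold = x$assignments)
}

#' Turn biomarker panels into model feature windows
#'
#' For each panel, simulates `windows_per_panel` short sensor recordings:
#' a 6-channel x `t_len` array of raw signals (current density for the
#' enzymatic channels, potential for the ion/pH channels) at 1 Hz, each
#' sample being the channel's forward-model steady state plus its Gaussian
#' sensor noise. Because the diet groups are exchangeable at week 0 (the
#' pre-diet baseline), week-0 panels are excluded by default.
#'
#' @param panels panel tibble from [simulate_chronic()].
#' @param params channel parameter list (default device parameterisation).
#' @param t_len samples per window (default 60, i.e. one minute at 1 Hz).
#' @param windows_per_panel recordings simulated per panel.
#' @param include_baseline_week keep week-0 panels (default `FALSE`).
#' @param seed integer seed.
#' @return a tibble with list-column `x` (6 x `t_len` matrices, rows named
#'   by channel), `class_label` (factor), `degree_label`, `subject_id`,
#'   `week`, `sample_id` and `window_id`.
#' @export
make_feature_windows <- function(panels,
                                 params = default_channel_params(),
                                 t_len = 60, windows_per_panel = 5,
                                 include_baseline_week = FALSE,
                                 seed = 1L) {
  if (!include_baseline_week) {
    panels <- panels[is.na(panels$week) | panels$week > 0, ]
  }
  if (!nrow(panels)) stop("no panels left to window", call. = FALSE)
  chans <- analyte_channels()
  cols <- panel_value_cols()
  groups <- sort(unique(panels$group))
  n_pan <- nrow(panels)
  n_win <- n_pan * windows_per_panel

  # steady-state signal per panel per channel (n_pan x 6)
  sig <- matrix(0, n_pan, 6, dimnames = list(NULL, chans))
  for (j in seq_along(chans)) {
    sig[, j] <- forward_signal(panels[[cols[j]]], params[[chans[j]]])
  }
  noise_sd <- vapply(params, `[[`, numeric(1), "noise_sd")[chans]

  with_seed(seed, {
    xs <- vector("list", n_win)
    idx <- rep(seq_len(n_pan), each = windows_per_panel)
    for (w in seq_len(n_win)) {
      m <- sig[idx[w], ] +
        matrix(rnorm(6 * t_len, 0, noise_sd), 6, t_len)
      rownames(m) <- chans
      xs[[w]] <- m
    }
    tibble::tibble(
      x = xs,
      class_label = factor(panels$group[idx], levels = groups),
      degree_label = panels$degree[idx],
      subject_id = panels$subject_id[idx],
      week = panels$week[idx],
      sample_id = panels$sample_id[idx],
      window_id = sprintf("%s_v%02d", panels$sample_id[idx],
                          sequence(rep(windows_per_panel, n_pan)))
    )
  })
}

# channel-wise scaler for window arrays; fitted on training windows only
fit_window_scaler <- function(windows_x) {
  all_mat <- do.call(cbind, windows_x)       # 6 x (N*T)
  mu <- rowMeans(all_mat)
  sdev <- sqrt(rowMeans((all_mat - mu)^2))
  if (any(sdev == 0)) {
    stop("constant channel in the training windows: ",
         paste(rownames(all_mat)[sdev == 0], collapse = ", "),
         call. = FALSE)
  }
  list(mean = mu, sd = sdev, fit_on = "train")
}

apply_window_scaler <- function(windows_x, scaler) {
  lapply(windows_x, function(m) (m - scaler$mean) / scaler$sd)
}
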