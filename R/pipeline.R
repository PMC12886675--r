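#' Pipeline configuration
#'
#' Configuration of the reproducible default experiment: simulate the
#' chronic cohort, synthesize sensor windows, calibrate the channels,
#' train the multi-task CNN under stratified fivefold cross-validation,
#' evaluate, and attribute. The default scales the cohort to 25 animals
#' per group with 5 windows per weekly panel over weeks 1-4, i.e. about
#' 1,500 windows (500 per group).
#'
#' @param n_per_group animals per group for the ML cohort.
#' @param weeks post-baseline weeks (must be >= 1 so that post-baseline
#'   windows exist).
#' @param t_len,windows_per_panel window shape (see
#'   [make_feature_windows()]).
#' @param k cross-validation folds.
#' @param mtl an [mtl_config()].
#' @param baselines run the classical-ML comparison.
#' @param shap_windows windows to attribute (0 disables).
#' @param seed master seed; stage seeds are derived from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = 25, weeks = 4, t_len = 60,
                            windows_per_panel = 5, k = 5,
                            mtl = mtl_config(), baselines = TRUE,
                            shap_windows = 60, seed = 1L) {
  structure(
    list(n_per_group = n_per_group, weeks = weeks, t_len = t_len,
         windows_per_panel = windows_per_panel, k = k, mtl = mtl,
         baselines = baselines, shap_windows = shap_windows,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys are the arguments of [pipeline_config()]
#'   (with `mtl` a nested map of [mtl_config()] arguments).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mtl_args <- raw$mtl %||% list()
  raw$mtl <- do.call(mtl_config, mtl_args)
  do.call(pipeline_config, raw)
}

#' Run the end-to-end default experiment
#'
#' Chains simulate -> sense -> calibrate -> fold -> train -> evaluate ->
#' explain, writing every artifact into `out_dir`: panel CSV + JSON
#' manifest, example trace CSV, calibration JSON, fold CSV, per-fold model
#' checkpoints, metrics JSON, training-history CSV, attribution CSVs and a
#' run manifest with seeds, artifact hashes and stage timings. Any stage
#' failure aborts with the stage name; artifacts of completed stages are
#' retained and the failure is recorded in `manifest_failed.json`.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param out_dir writable output directory (created if missing).
#' @return the run manifest (list), invisibly; the manifest is also
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  manifest <- list(seed = config$seed, config = rapply(
    unclass(config), identity, how = "list"))

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$failed_stage <- name
      manifest$error <- conditionMessage(e)
      jsonlite::write_json(manifest,
                           file.path(out_dir, "manifest_failed.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    message(sprintf("[%s] done in %.1f s (seed %d)", name,
                    timings[[name]], config$seed))
    res
  }

  panels <- stage("simulate", {
    if (config$weeks < 1) {
      stop("`weeks` must be >= 1: with weeks = 0 only the pre-diet ",
           "baseline exists and the groups are indistinguishable")
    }
    cc <- cohort_config(n_per_group = config$n_per_group,
                        weeks = config$weeks,
                        seed = child_seed(config$seed, 1))
    p <- simulate_chronic(cc)
    write_panels(p, file.path(out_dir, "panels.csv"), config = cc)
    p
  })

  windows <- stage("sense", {
    w <- make_feature_windows(panels, t_len = config$t_len,
                              windows_per_panel = config$windows_per_panel,
                              seed = child_seed(config$seed, 2))
    # a representative trace per channel for inspection
    pars <- default_channel_params()
    tr <- dplyr::bind_rows(lapply(names(pars), function(ch) {
      p <- pars[[ch]]
      mid <- mean(p$linear_range)
      f <- if (p$modality == "amperometric") amperometric_forward else
        potentiometric_forward
      f(mid, p, duration_s = 60, seed = child_seed(config$seed, 3))
    }))
    utils::write.csv(tr, file.path(out_dir, "traces.csv"),
                     row.names = FALSE)
    w
  })

  stage("calibrate", {
    curves <- calibrate_all_channels()
    write_calibration_json(curves, file.path(out_dir, "calibration.json"))
  })

  folds <- stage("fold", {
    fa <- make_stratified_folds(windows$class_label, windows$degree_label,
                                k = config$k,
                                seed = child_seed(config$seed, 4),
                                subject_ids = windows$subject_id)
    utils::write.csv(
      data.frame(window_id = windows$window_id, fold = fa$assignments),
      file.path(out_dir, "folds.csv"), row.names = FALSE)
    fa
  })

  cv <- stage("train", {
    cfg <- config$mtl
    cfg$seed <- child_seed(config$seed, 5)
    fit <- train_mtl(windows, folds, cfg)
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    for (f in seq_along(fit$models)) {
      saveRDS(fit$models[[f]],
              file.path(out_dir, sprintf("model_fold%d.rds", f)))
    }
    fit
  })

  metrics <- stage("evaluate", {
    # pooled out-of-fold predictions
    preds <- vector("list", folds$k)
    for (f in seq_len(folds$k)) {
      va <- which(folds$assignments == f)
      pr <- predict(cv$models[[f]], windows[va, ])
      pr$.row <- va
      preds[[f]] <- pr
    }
    oof <- dplyr::arrange(dplyr::bind_rows(preds), .data$.row)
    probs <- as.matrix(oof[paste0(".prob_",
                                  levels(windows$class_label))])
    cm <- classification_metrics(windows$class_label, probs)
    rm_ <- regression_metrics(windows$degree_label, oof$.pred_degree)
    out <- list(
      fold_mean_accuracy = mean(cv$metrics$val_accuracy),
      fold_mean_r2 = mean(cv$metrics$val_r2),
      pooled = c(cm[c("accuracy", "macro_precision", "macro_recall",
                      "macro_f1")], rm_)
    )
    if (config$baselines) {
      bl <- train_baselines(windows, folds,
                            seed = child_seed(config$seed, 6))
      out$baselines <- attr(bl, "summary")
    }
    jsonlite::write_json(out, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(as.data.frame(cm$confusion),
                     file.path(out_dir, "confusion.csv"))
    out
  })

  if (config$shap_windows > 0) {
    stage("explain", {
      rep1 <- shap_report(cv$models[[1]],
                          windows[folds$assignments == 1, ],
                          max_windows = config$shap_windows,
                          seed = child_seed(config$seed, 7))
      utils::write.csv(rep1, file.path(out_dir, "shap_values.csv"),
                       row.names = FALSE)
      sm <- shap_summary(rep1)
      utils::write.csv(sm$ranking, file.path(out_dir, "shap_ranking.csv"),
                       row.names = FALSE)
    })
  }

  manifest$metrics <- metrics[c("fold_mean_accuracy", "fold_mean_r2")]
  manifest$timings_s <- timings
  files <- list.files(out_dir, full.names = TRUE)
  manifest$artifacts <- as.list(tools::md5sum(
    files[!grepl("manifest", files)]))
  names(manifest$artifacts) <- basename(names(manifest$artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Dynamic two-state monitoring demonstration
#'
#' Emulates moving the patch between animals in different health states:
#' two consecutive monitoring segments are simulated (by default an
#' HFFD-like state followed by an HFFSD-like state at the final study
#' week), windowed, and streamed through a trained model. Reports the
#' prediction stream and, per segment, the fraction of windows whose
#' predicted class matches the generating group.
#'
#' @param model a trained `mtl_model`.
#' @param groups length-2 character, the generating group of each segment.
#' @param n_windows windows per segment (one per minute).
#' @param week the cohort week whose state is simulated.
#' @param seed integer seed.
#' @param cohort a [cohort_config()] describing the generating state.
#' @return tibble `segment, group, time_min, pred_class, pred_degree`
#'   with attribute `segment_match` (named fraction per segment).
#' @export
dynamic_transfer_demo <- function(model, groups = c("HFFD", "HFFSD"),
                                  n_windows = 20, week = NULL, seed = 1L,
                                  cohort = cohort_config()) {
  stopifnot(inherits(model, "mtl_model"), length(groups) == 2)
  if (n_windows < 1) stop("segments must contain at least one window",
                          call. = FALSE)
  week <- week %||% cohort$weeks
  streams <- list()
  for (s in 1:2) {
    g <- groups[s]
    panels <- segment_panels(g, week, cohort, n_windows,
                             seed = child_seed(seed, s))
    w <- make_feature_windows(panels, t_len = model$t_len,
                              windows_per_panel = 1,
                              include_baseline_week = TRUE,
                              seed = child_seed(seed, s + 10))
    pr <- predict(model, w)
    streams[[s]] <- tibble::tibble(
      segment = s, group = g,
      time_min = (s - 1) * n_windows + seq_len(n_windows) - 1,
      pred_class = pr$.pred_class, pred_degree = pr$.pred_degree
    )
  }
  out <- dplyr::bind_rows(streams)
  match_frac <- vapply(1:2, function(s) {
    seg <- out[out$segment == s, ]
    mean(as.character(seg$pred_class) == seg$group)
  }, numeric(1))
  names(match_frac) <- groups
  attr(out, "segment_match") <- match_frac
  out
}

# one animal held in the week-`week` state of `group`, re-measured
# n_times; panels drawn with the chronic generator's noise structure
segment_panels <- function(group, week, cohort, n_times, seed) {
  if (!group %in% names(cohort$effect_rates)) {
    stop("unknown group `", group, "`", call. = FALSE)
  }
  rng <- sensor_ranges()
  with_seed(seed, {
    intercept <- correlated_deviates(
      cohort$animal_sd_frac * cohort$baseline_sds,
      cohort$glucose_cholesterol_rho)
    mu <- cohort$baseline_means + cohort$effect_rates[[group]] * week
    rows <- lapply(seq_len(n_times), function(i) {
      eps <- correlated_deviates(cohort$baseline_sds,
                                 cohort$glucose_cholesterol_rho)
      val <- mu + intercept + eps
      for (ch in analyte_channels()) {
        val[ch] <- min(max(val[ch], rng[[ch]][1]), rng[[ch]][2])
      }
      deg <- severity(group, week, cohort) +
        rnorm(1, 0, cohort$degree_noise_sd)
      tibble::tibble(
        sample_id = sprintf("%s_seg_%03d", group, i), group = group,
        week = week, time_min = i - 1,
        glucose_mM = val[["glucose"]], ua_uM = val[["ua"]],
        cholesterol_mM = val[["cholesterol"]], na_mM = val[["na"]],
        k_mM = val[["k"]], ph = val[["ph"]],
        degree = min(max(deg, 0), 1),
        subject_id = paste0(group, "_seg")
      )
    })
    dplyr::bind_rows(rows)
  })
}
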