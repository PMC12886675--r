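#' Per-event selectivity drift
#'
#' Relative signal change around each interferent-addition event:
#' `100 * (post-event mean - pre-event mean) / pre-event mean`, with the
#' pre window ending and the post window starting a guard interval away
#' from the event so the mixing transient does not contaminate either
#' window.
#'
#' @param trace a [sensor_trace()].
#' @param event_times event times in seconds, inside the trace span.
#' @param window_s pre/post window length (default 30 s).
#' @param guard_s gap between each window and the event (default 5 s).
#' @return numeric vector of percentage drifts, one per event.
#' @export
selectivity_drift <- function(trace, event_times, window_s = 30,
                              guard_s = 5) {
  stopifnot(inherits(trace, "sensor_trace"))
  if (any(event_times <= min(trace$t_s) | event_times >= max(trace$t_s))) {
    stop("all `event_times` must lie strictly inside the trace span",
         call. = FALSE)
  }
  vapply(event_times, function(ev) {
    pre <- trace$y[trace$t_s >= ev - guard_s - window_s &
                     trace$t_s <= ev - guard_s]
    post <- trace$y[trace$t_s >= ev + guard_s &
                      trace$t_s <= ev + guard_s + window_s]
    if (!length(pre) || !length(post)) {
      stop("event at ", ev, " s leaves an empty pre/post window",
           call. = FALSE)
    }
    m_pre <- mean(pre)
    if (m_pre == 0) {
      stop("pre-event mean is zero at event ", ev, " s; relative drift ",
           "undefined", call. = FALSE)
    }
    100 * (mean(post) - m_pre) / m_pre
  }, numeric(1))
}

#' Long-run signal retention
#'
#' `100 * (final-window mean) / (initial-window mean)` over a trace —
#' the operational-stability statistic of a long continuous measurement.
#'
#' @param trace a [sensor_trace()].
#' @param window_s window length at each end (default 60 s).
#' @return retention percentage.
#' @export
signal_retention <- function(trace, window_s = 60) {
  stopifnot(inherits(trace, "sensor_trace"))
  span <- max(trace$t_s) - min(trace$t_s)
  if (span < 2 * window_s) {
    stop("trace shorter than two ", window_s, "-s windows", call. = FALSE)
  }
  first <- mean(trace$y[trace$t_s <= min(trace$t_s) + window_s])
  if (first == 0) stop("initial-window mean is zero", call. = FALSE)
  last <- mean(trace$y[trace$t_s >= max(trace$t_s) - window_s])
  100 * last / first
}

#' Relative standard deviation
#'
#' `100 * sample SD (ddof = 1) / mean` — the reproducibility statistic used
#' for sensor-to-sensor and batch comparisons. Scale-invariant under
#' positive scaling.
#'
#' @param values numeric vector, n >= 2, nonzero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(1, 2, 3))  # 50
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; RSD undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Biomarker Pearson correlation matrix
#'
#' 6 x 6 Pearson correlation matrix of the analyte columns of a panel
#' table — the data behind the biomarker correlation chord diagram.
#'
#' @param panels panel tibble with the six analyte columns.
#' @return symmetric 6 x 6 matrix with unit diagonal, dimnames set to the
#'   channel names.
#' @export
pearson_matrix <- function(panels) {
  cols <- panel_value_cols()
  missing <- setdiff(cols, names(panels))
  if (length(missing)) {
    stop("panel table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(panels) < 3L) stop("need at least 3 panels", call. = FALSE)
  x <- as.matrix(panels[cols])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant channel(s): ",
         paste(cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  m <- stats::cor(x)
  dimnames(m) <- list(analyte_channels(), analyte_channels())
  m
}

#' Selectivity scenario through the sensor twin
#'
#' Builds the stepwise interferent-addition trace used by the selectivity
#' test: the channel sits at a target concentration; at each event time one
#' interferent from the standard panel is added and the signal shifts by
#' its additive cross-term.
#'
#' @param params a [channel_params()].
#' @param conc_target target concentration held throughout.
#' @param interferents named concentrations (default
#'   [default_interferent_panel()] for the channel).
#' @param step_s seconds between additions.
#' @param seed seed for the noise stream.
#' @return list with `trace` (a [sensor_trace()]) and `event_times`.
#' @export
selectivity_scenario <- function(params, conc_target,
                                 interferents =
                                   default_interferent_panel(params$channel),
                                 step_s = 120, seed = 1L) {
  n_ev <- length(interferents)
  duration <- step_s * (n_ev + 1)
  fwd <- if (params$modality == "amperometric") {
    amperometric_forward
  } else {
    potentiometric_forward
  }
  tr <- fwd(conc_target, params, duration_s = duration, seed = seed)
  event_times <- step_s * seq_len(n_ev)
  y <- tr$y
  for (i in seq_len(n_ev)) {
    delta <- apply_interference(conc_target, interferents[i], params)
    y[tr$t_s >= event_times[i]] <- y[tr$t_s >= event_times[i]] + delta
  }
  tr$y <- y
  list(trace = tr, event_times = event_times)
}

#' Operational-stability scenario through the sensor twin
#'
#' A 120-min continuous measurement at a fixed concentration with the
#' documented default baseline drift (-0.04% of the initial signal per
#' minute), the scenario against which the >= 88% signal-retention pass
#' criterion is evaluated.
#'
#' @param params a [channel_params()].
#' @param conc_target held concentration.
#' @param duration_min scenario length (default 120 min).
#' @param drift_frac_per_min signed fractional drift per minute (default
#'   -4e-4).
#' @param seed noise seed.
#' @return a [sensor_trace()].
#' @export
stability_scenario <- function(params, conc_target, duration_min = 120,
                               drift_frac_per_min = -4e-4, seed = 1L) {
  fwd <- if (params$modality == "amperometric") {
    amperometric_forward
  } else {
    potentiometric_forward
  }
  tr <- fwd(conc_target, params, duration_s = duration_min * 60,
            seed = seed)
  base <- forward_signal(conc_target, params)
  add_artifacts(tr, drift_rate = drift_frac_per_min * base)
}
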