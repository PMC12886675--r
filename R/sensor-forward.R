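#' Sensor traces
#'
#' A sensor trace is a tibble with one row per sample: `channel`, `t_s`
#' (seconds, uniformly spaced), `y` (current density in uA cm-2 or potential
#' in mV), `unit`, and `saturated` (logical, `TRUE` where the commanded
#' concentration fell outside the channel's linear range and the emitted
#' signal was pinned to the range edge). The sampling rate and provenance
#' are carried in the `sample_rate_hz` and `meta` attributes.
#'
#' @param channel channel name.
#' @param t_s numeric vector of sample times in seconds, uniformly spaced.
#' @param y signal values, same length as `t_s`.
#' @param unit signal unit string.
#' @param saturated logical scalar or vector.
#' @param meta named list of provenance (seed, params, ...).
#' @return a tibble of class `sensor_trace`.
#' @export
sensor_trace <- function(channel, t_s, y, unit, saturated = FALSE,
                         meta = list()) {
  n <- length(t_s)
  if (n < 2L || length(y) != n) {
    stop("a trace needs at least 2 samples and len(t) == len(y)",
         call. = FALSE)
  }
  dt <- diff(t_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9) {
    stop("`t_s` must be strictly increasing and uniformly sampled",
         call. = FALSE)
  }
  out <- tibble::tibble(
    channel = channel, t_s = as.numeric(t_s), y = as.numeric(y),
    unit = unit, saturated = rep_len(saturated, n)
  )
  attr(out, "sample_rate_hz") <- 1 / dt[1]
  attr(out, "meta") <- meta
  class(out) <- c("sensor_trace", class(out))
  out
}

trace_unit <- function(params) {
  if (params$modality == "amperometric") "uA_cm2" else "mV"
}

# noiseless steady-state forward law shared by both modalities
forward_signal <- function(conc, params) {
  switch(params$modality,
    amperometric = params$intercept + params$slope * conc,
    potentiometric = params$intercept +
      params$slope * log10(conc / params$ref_conc),
    ph = params$intercept - params$slope * conc
  )
}

#' Chronoamperometric forward model
#'
#' Simulates the current-density trace of an enzymatic (amperometric)
#' channel held at fixed potential: a steady state
#' `intercept + slope * conc`, an optional initial exponential transient
#' that decays within `settle_s`, additive Gaussian noise and linear drift.
#' Concentrations outside the linear range saturate: the emitted signal is
#' the range-edge value and the trace is flagged `saturated`.
#'
#' @param conc analyte concentration in the channel's units.
#' @param params a [channel_params()] with `modality = "amperometric"`.
#' @param duration_s trace length in seconds.
#' @param seed integer seed, or `NULL` to draw from the session RNG.
#' @param sample_rate_hz sampling rate (default 1 Hz).
#' @param transient_amplitude initial excess current that decays
#'   exponentially; 0 disables the transient.
#' @param settle_s time constant budget of the transient: the decay constant
#'   is `settle_s / 5` so the transient is <1% after `settle_s`.
#' @return a [sensor_trace()].
#' @examples
#' p <- default_channel_params(noiseless = TRUE)$glucose
#' tr <- amperometric_forward(5, p, duration_s = 60, seed = 1)
#' steady_state(tr, window_s = 30)  # ~ 0.1122 * 5
#' @export
amperometric_forward <- function(conc, params, duration_s = 60, seed = NULL,
                                 sample_rate_hz = 1,
                                 transient_amplitude = 0, settle_s = 30) {
  stopifnot(inherits(params, "channel_params"))
  if (params$modality != "amperometric") {
    stop("`params` is not an amperometric channel", call. = FALSE)
  }
  sat <- conc < params$linear_range[1] || conc > params$linear_range[2]
  conc_eff <- min(max(conc, params$linear_range[1]), params$linear_range[2])
  simulate_trace(conc_eff, params, duration_s, seed, sample_rate_hz,
                 transient_amplitude, settle_s, saturated = sat)
}

#' Potentiometric forward model
#'
#' Simulates the open-circuit-potential trace of an ion-selective channel,
#' `E = intercept + slope * log10(conc / ref_conc)` (so a tenfold
#' concentration step changes the potential by exactly `slope` mV), or of
#' the pH channel, `E = intercept - slope * pH`.
#'
#' @inheritParams amperometric_forward
#' @param conc ion concentration (mM, must be > 0) or pH value.
#' @return a [sensor_trace()].
#' @examples
#' p <- default_channel_params(noiseless = TRUE)$na
#' e10 <- steady_state(potentiometric_forward(10, p, 60), 30)
#' e100 <- steady_state(potentiometric_forward(100, p, 60), 30)
#' e100 - e10  # = 52.87 mV, one decade
#' @export
potentiometric_forward <- function(conc, params, duration_s = 60,
                                   seed = NULL, sample_rate_hz = 1,
                                   transient_amplitude = 0, settle_s = 30) {
  stopifnot(inherits(params, "channel_params"))
  if (!params$modality %in% c("potentiometric", "ph")) {
    stop("`params` is not a potentiometric or pH channel", call. = FALSE)
  }
  if (params$modality == "potentiometric" && conc <= 0) {
    stop("ion concentration must be positive", call. = FALSE)
  }
  sat <- conc < params$linear_range[1] || conc > params$linear_range[2]
  conc_eff <- min(max(conc, params$linear_range[1]), params$linear_range[2])
  simulate_trace(conc_eff, params, duration_s, seed, sample_rate_hz,
                 transient_amplitude, settle_s, saturated = sat)
}

simulate_trace <- function(conc, params, duration_s, seed, sample_rate_hz,
                           transient_amplitude, settle_s, saturated) {
  if (duration_s * sample_rate_hz < 2) {
    stop("trace must contain at least 2 samples", call. = FALSE)
  }
  t_s <- seq(0, duration_s, by = 1 / sample_rate_hz)
  base <- forward_signal(conc, params)
  y <- rep(base, length(t_s))
  if (transient_amplitude != 0) {
    y <- y + transient_amplitude * exp(-t_s / (settle_s / 5))
  }
  if (params$drift_rate != 0) y <- y + params$drift_rate * t_s / 60
  if (params$noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(length(t_s), 0, params$noise_sd))
  }
  sensor_trace(params$channel, t_s, y, trace_unit(params),
               saturated = saturated,
               meta = list(seed = seed, conc = conc,
                           slope = params$slope))
}

#' Steady-state readout of a trace
#'
#' Mean signal over the trailing window of a trace — the readout that feeds
#' calibration, taken after the chronoamperometric transient has settled.
#'
#' @param trace a [sensor_trace()].
#' @param window_s trailing window length in seconds.
#' @return scalar readout in the trace's signal units.
#' @export
steady_state <- function(trace, window_s) {
  stopifnot(inherits(trace, "sensor_trace"))
  span <- max(trace$t_s) - min(trace$t_s)
  if (window_s > span) {
    stop("`window_s` (", window_s, " s) exceeds the trace span (", span,
         " s)", call. = FALSE)
  }
  mean(trace$y[trace$t_s >= max(trace$t_s) - window_s])
}

#' Additive interference model
#'
#' Signal offset produced by non-target species, modelled as additive
#' cross-terms `delta = sum_j alpha_j * C_j` with per-channel coefficients
#' `alpha` stored in the channel's `interference_coeffs`. With the default
#' coefficients the relative drift `|delta| / (slope * conc_target)` stays
#' within 6% for the standard interferent panel.
#'
#' @param conc_target target-analyte concentration (used only by callers to
#'   express the offset relative to the target signal).
#' @param interferents named numeric vector of interferent concentrations,
#'   in the units the channel's coefficients are expressed in.
#' @param params a [channel_params()].
#' @return scalar signal offset, in the channel's signal units.
#' @examples
#' p <- default_channel_params()$glucose
#' apply_interference(5, c(ascorbic_acid = 0.3, uric_acid = 0.3), p)
#' @export
apply_interference <- function(conc_target, interferents, params) {
  stopifnot(inherits(params, "channel_params"))
  if (length(interferents) == 0L) return(0)
  if (any(interferents < 0)) {
    stop("interferent concentrations must be non-negative", call. = FALSE)
  }
  known <- names(params$interference_coeffs)
  unknown <- setdiff(names(interferents), known)
  if (length(unknown)) {
    stop("unknown interferent(s) ", paste(unknown, collapse = ", "),
         " for channel ", params$channel, "; known: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  sum(params$interference_coeffs[names(interferents)] * interferents)
}

#' Standard interferent panel
#'
#' The in-vitro selectivity scenario: species commonly present in
#' interstitial fluid, at the stepwise-addition concentrations used for the
#' selectivity test (ascorbic acid 0.3 mM, uric acid 0.3 mM, lactate 5 mM,
#' urea 5 mM for the enzymatic channels; Na+/K+/NH4+ steps for the ion
#' channels).
#'
#' @param channel channel name.
#' @return named numeric vector of interferent concentrations.
#' @export
default_interferent_panel <- function(channel) {
  channel <- match.arg(channel, analyte_channels())
  switch(channel,
    glucose = c(ascorbic_acid = 0.3, uric_acid = 0.3, lactate = 5,
                urea = 5),
    ua = c(ascorbic_acid = 0.3, glucose = 5, lactate = 5, urea = 5),
    cholesterol = c(ascorbic_acid = 0.3, uric_acid = 0.3, lactate = 5,
                    urea = 5),
    na = c(potassium = 4.5, ammonium = 1),
    k = c(sodium = 140, ammonium = 1),
    ph = c(sodium = 140, potassium = 4.5)
  )
}

#' Add drift and motion artifacts to a trace
#'
#' Pure transform `y' = y + drift_rate * t / 60 + sum of spikes`. Motion
#' artifacts are short Gaussian-shaped transients of the given amplitude at
#' the given times (0.5 s SD), emulating the signal excursions produced by
#' skin deformation during movement. The documented comparison scenario
#' between a strain-isolated and a non-isolated patch uses a 4:1 spike
#' amplitude ratio.
#'
#' @param trace a [sensor_trace()].
#' @param drift_rate linear drift, signal units per minute.
#' @param motion `NULL`, or a list with `amplitude` (signal units) and
#'   `times` (seconds); optional `width_s` (default 0.5).
#' @param seed unused unless `motion$jitter_sd` is set; kept for a stable
#'   signature across stochastic transforms.
#' @return the transformed [sensor_trace()].
#' @export
add_artifacts <- function(trace, drift_rate = 0, motion = NULL, seed = NULL) {
  stopifnot(inherits(trace, "sensor_trace"))
  y <- trace$y + drift_rate * trace$t_s / 60
  if (!is.null(motion) && length(motion$times)) {
    width <- motion$width_s %||% 0.5
    for (tm in motion$times) {
      y <- y + motion$amplitude * exp(-0.5 * ((trace$t_s - tm) / width)^2)
    }
  }
  out <- trace
  out$y <- y
  out
}

#' @method autoplot sensor_trace
#' @export
autoplot.sensor_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_s, y = .data$y)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)",
                  y = paste0("signal (", object$unit[1], ")"),
                  title = paste("channel:", object$channel[1])) +
    ggplot2::theme_minimal()
}
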