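#' Sensor channel parameters
#'
#' A `channel_params` object holds the forward-model parameters of one
#' electrochemical channel of the patch. Amperometric channels (glucose,
#' uric acid, cholesterol) follow a linear chronoamperometric law
#' `y = intercept + slope * conc` in current density (uA cm-2);
#' potentiometric ion channels (Na+, K+) follow the Nernstian decade law
#' `E = intercept + slope * log10(conc / ref_conc)` in mV; the pH channel is
#' linear in pH with a negative response, `E = intercept - slope * pH`.
#'
#' @param channel one of `"glucose"`, `"ua"`, `"cholesterol"`, `"na"`, `"k"`,
#'   `"ph"`.
#' @param modality `"amperometric"`, `"potentiometric"` or `"ph"`.
#' @param slope sensitivity, strictly positive. Units: uA cm-2 per analyte
#'   unit (amperometric), mV per decade (potentiometric), mV per pH unit (ph).
#' @param intercept baseline signal (uA cm-2) or standard potential E0 (mV).
#' @param ref_conc reference concentration (mM) anchoring the decade law;
#'   ignored for non-ion channels.
#' @param noise_sd additive Gaussian noise SD, in signal units.
#' @param drift_rate baseline drift, signal units per minute.
#' @param interference_coeffs named numeric vector: signal units per unit
#'   concentration of each known interferent.
#' @param linear_range length-2 numeric, lower and upper bound of the linear
#'   response range in analyte units.
#' @return an object of class `channel_params`.
#' @examples
#' p <- channel_params("glucose", "amperometric", slope = 0.1122,
#'                     linear_range = c(0, 20))
#' p$slope
#' @export
channel_params <- function(channel,
                           modality,
                           slope,
                           intercept = 0,
                           ref_conc = 1,
                           noise_sd = 0,
                           drift_rate = 0,
                           interference_coeffs = numeric(),
                           linear_range) {
  channel <- match.arg(channel, analyte_channels())
  modality <- match.arg(modality, c("amperometric", "potentiometric", "ph"))
  stopifnot(is.numeric(slope), length(slope) == 1L)
  if (slope <= 0) stop("`slope` must be strictly positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  stopifnot(length(linear_range) == 2L)
  if (linear_range[1] >= linear_range[2]) {
    stop("`linear_range` must satisfy lo < hi", call. = FALSE)
  }
  if (length(interference_coeffs) &&
      is.null(names(interference_coeffs))) {
    stop("`interference_coeffs` must be a named vector", call. = FALSE)
  }
  structure(
    list(
      channel = channel, modality = modality, slope = slope,
      intercept = intercept, ref_conc = ref_conc, noise_sd = noise_sd,
      drift_rate = drift_rate, interference_coeffs = interference_coeffs,
      linear_range = as.numeric(linear_range)
    ),
    class = "channel_params"
  )
}

#' @export
print.channel_params <- function(x, ...) {
  unit <- switch(x$modality,
    amperometric = "uA cm-2 per analyte unit",
    potentiometric = "mV per decade",
    ph = "mV per pH unit"
  )
  cat("<channel_params> ", x$channel, " [", x$modality, "]\n", sep = "")
  cat("  slope: ", x$slope, " ", unit, ";  intercept: ", x$intercept, "\n",
      sep = "")
  cat("  noise SD: ", x$noise_sd, ";  linear range: [",
      x$linear_range[1], ", ", x$linear_range[2], "]\n", sep = "")
  invisible(x)
}

analyte_channels <- function() c("glucose", "ua", "cholesterol", "na", "k", "ph")

#' Default channel parameterisation of the six-analyte patch
#'
#' Returns the forward-model parameters of all six channels, parameterised
#' from the device's reported calibrations: amperometric sensitivities of
#' 0.1122 uA cm-2 mM-1 (glucose), 0.001395 uA cm-2 uM-1 (uric acid) and
#' 0.1637 uA cm-2 mM-1 (cholesterol); near-Nernstian slopes of 52.87 mV per
#' decade (Na+) and 58.46 mV per decade (K+); and a 57.61 mV per pH unit
#' linear pH response. Linear ranges follow the calibration ladders
#' (glucose 0-20 mM, UA 0-1000 uM, cholesterol 0-10 mM, Na+ 5-160 mM,
#' K+ 1-32 mM, pH 3-8).
#'
#' Baseline noise SDs are free parameters of the twin (they are not reported
#' for the device); the defaults are fixed so that the detection limit
#' `3.3 * sigma / S` of each amperometric channel lands on the reported LODs
#' (0.39 mM, 2.7 uM, 0.52 mM). Ion/pH channels default to 0.5 mV noise.
#'
#' @param noiseless if `TRUE`, zero out all noise, drift and interference
#'   terms (useful for calibration round trips).
#' @return a named list of [channel_params()] objects, one per channel.
#' @examples
#' pars <- default_channel_params()
#' pars$glucose$slope
#' @export
default_channel_params <- function(noiseless = FALSE) {
  pars <- list(
    glucose = channel_params(
      "glucose", "amperometric",
      slope = 0.1122, intercept = 0,
      noise_sd = 0.39 * 0.1122 / 3.3,
      interference_coeffs = c(
        ascorbic_acid = 0.020, uric_acid = 0.020, lactate = 0.0020,
        urea = 0.0004
      ),
      linear_range = c(0, 20)
    ),
    ua = channel_params(
      "ua", "amperometric",
      slope = 0.001395, intercept = 0,
      noise_sd = 2.7 * 0.001395 / 3.3,
      interference_coeffs = c(
        ascorbic_acid = 0.020, glucose = 0.0016, lactate = 0.0008,
        urea = 0.0002
      ),
      linear_range = c(0, 1000)
    ),
    cholesterol = channel_params(
      "cholesterol", "amperometric",
      slope = 0.1637, intercept = 0,
      noise_sd = 0.52 * 0.1637 / 3.3,
      interference_coeffs = c(
        ascorbic_acid = 0.030, uric_acid = 0.030, lactate = 0.0030,
        urea = 0.0006
      ),
      linear_range = c(0, 10)
    ),
    na = channel_params(
      "na", "potentiometric",
      slope = 52.87, intercept = 250, ref_conc = 1, noise_sd = 0.5,
      interference_coeffs = c(potassium = 0.5, ammonium = 0.3),
      linear_range = c(5, 160)
    ),
    k = channel_params(
      "k", "potentiometric",
      slope = 58.46, intercept = 180, ref_conc = 1, noise_sd = 0.5,
      interference_coeffs = c(sodium = 0.02, ammonium = 0.4),
      linear_range = c(1, 32)
    ),
    ph = channel_params(
      "ph", "ph",
      slope = 57.61, intercept = 600, noise_sd = 0.5,
      interference_coeffs = c(sodium = 0.005, potassium = 0.05),
      linear_range = c(3, 8)
    )
  )
  if (noiseless) {
    pars <- lapply(pars, function(p) {
      p$noise_sd <- 0
      p$drift_rate <- 0
      p
    })
  }
  pars
}

# physiological baseline ranges used to validate cohort configs
physiological_ranges <- function() {
  tibble::tribble(
    ~channel,      ~lo,   ~hi,
    "glucose",     4.4,   6.6,
    "ua",          130,   460,
    "cholesterol", 2.9,   5.2,
    "na",          135,   145,
    "k",           3.5,   5.0,
    "ph",          6.6,   7.6
  )
}

# sensor linear ranges as a lookup used by the cohort generator
sensor_ranges <- function() {
  list(glucose = c(0, 20), ua = c(0, 1000), cholesterol = c(0, 10),
       na = c(5, 160), k = c(1, 32), ph = c(3, 8))
}

#' Write / read channel parameters as YAML
#'
#' Serialises a list of [channel_params()] to a YAML file keyed by channel,
#' with units embedded in the field names, and reads it back.
#'
#' @param params named list of `channel_params`.
#' @param path file path.
#' @return `write_channel_params()` returns `path` invisibly;
#'   `read_channel_params()` returns the named list of `channel_params`.
#' @export
write_channel_params <- function(params, path) {
  out <- lapply(params, function(p) {
    list(
      modality = p$modality,
      slope_signal_per_unit = p$slope,
      intercept_signal = p$intercept,
      ref_conc_mM = p$ref_conc,
      noise_sd_signal = p$noise_sd,
      drift_rate_signal_per_min = p$drift_rate,
      interference_coeffs = as.list(p$interference_coeffs),
      linear_range = p$linear_range
    )
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_channel_params
#' @export
read_channel_params <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(ch) {
    r <- raw[[ch]]
    channel_params(
      channel = ch, modality = r$modality,
      slope = r$slope_signal_per_unit, intercept = r$intercept_signal,
      ref_conc = r$ref_conc_mM, noise_sd = r$noise_sd_signal,
      drift_rate = r$drift_rate_signal_per_min,
      interference_coeffs = unlist(r$interference_coeffs) %||% numeric(),
      linear_range = unlist(r$linear_range)
    )
  })
  names(out) <- names(raw)
  out
}
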