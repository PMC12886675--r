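#' Calibration curves
#'
#' A `calibration_curve` is the fitted inverse model of one channel:
#' the ordinary-least-squares slope and intercept of readout on the
#' regressor (concentration for amperometric channels, log10 concentration
#' for ion channels, pH for the pH channel), the Pearson correlation `r` of
#' the fit, the residual noise SD `sigma` (ddof = 2, two fitted
#' parameters), and the detection limit `lod = 3.3 * sigma / |slope|`.
#'
#' @name calibration_curve
NULL

new_calibration_curve <- function(channel, modality, slope, intercept, r,
                                  sigma, lod, range, ref_conc = 1) {
  structure(
    list(channel = channel, modality = modality, slope = slope,
         intercept = intercept, r = r, sigma = sigma, lod = lod,
         range = range, ref_conc = ref_conc),
    class = "calibration_curve"
  )
}

# closed-form simple OLS used by both fitters
ols_fit <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 calibration points", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("all concentrations are identical; cannot fit a slope",
         call. = FALSE)
  }
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  sigma <- if (n > 2) sqrt(sum(resid^2) / (n - 2)) else 0
  syy <- sum((y - my)^2)
  r <- if (syy == 0) 1 else sxy / sqrt(sxx * syy)
  list(slope = slope, intercept = intercept, sigma = sigma, r = r)
}

#' Fit an amperometric calibration curve
#'
#' Ordinary least squares of steady-state current density on concentration.
#' `r` is the Pearson correlation of the points; `sigma` the residual SD
#' with ddof = 2; the LOD is `3.3 * sigma / slope`.
#'
#' @param conc concentration ladder (analyte units), at least 3 distinct
#'   values.
#' @param readout steady-state readouts (uA cm-2), same length.
#' @param channel channel name recorded on the curve.
#' @return a [calibration_curve].
#' @examples
#' fit_amperometric(0:10, 0.1637 * (0:10), channel = "cholesterol")$slope
#' @export
fit_amperometric <- function(conc, readout, channel = "glucose") {
  stopifnot(length(conc) == length(readout))
  f <- ols_fit(conc, readout)
  new_calibration_curve(
    channel = channel, modality = "amperometric", slope = f$slope,
    intercept = f$intercept, r = f$r, sigma = f$sigma,
    lod = if (f$slope > 0) 3.3 * f$sigma / f$slope else NA_real_,
    range = range(conc)
  )
}

#' Fit a potentiometric calibration curve
#'
#' For ion channels, ordinary least squares of potential on
#' `log10(conc / ref_conc)`, giving a slope in mV per decade; for the pH
#' channel, regression of potential on pH, giving mV per pH unit (the raw
#' slope is negative under the default sign convention — potential falls as
#' pH rises).
#'
#' @param conc concentration ladder in mM (ions, strictly positive) or pH
#'   values.
#' @param potential potentials in mV, same length.
#' @param modality `"potentiometric"` (ions) or `"ph"`.
#' @param channel channel name recorded on the curve.
#' @param ref_conc decade reference concentration (mM) anchoring the ion
#'   model.
#' @return a [calibration_curve]; for ion channels `lod` is in mM (from the
#'   decade model linearised at the lower range end).
#' @examples
#' conc <- c(5, 10, 20, 40, 80, 160)
#' fit_potentiometric(conc, 250 + 52.87 * log10(conc), channel = "na")$slope
#' @export
fit_potentiometric <- function(conc, potential,
                               modality = c("potentiometric", "ph"),
                               channel = "na", ref_conc = 1) {
  modality <- match.arg(modality)
  stopifnot(length(conc) == length(potential))
  if (modality == "potentiometric") {
    if (any(conc <= 0)) {
      stop("ion concentrations must be strictly positive", call. = FALSE)
    }
    x <- log10(conc / ref_conc)
  } else {
    x <- conc
  }
  f <- ols_fit(x, potential)
  new_calibration_curve(
    channel = channel, modality = modality, slope = f$slope,
    intercept = f$intercept, r = f$r, sigma = f$sigma,
    lod = if (f$slope != 0) 3.3 * f$sigma / abs(f$slope) else NA_real_,
    range = range(conc), ref_conc = ref_conc
  )
}

#' Limit of detection
#'
#' `lod = 3.3 * sigma / S`, where `sigma` is the baseline noise SD and `S`
#' the calibration slope. Homogeneous of degree 0: scaling both by the same
#' factor leaves the LOD unchanged.
#'
#' @param sigma baseline noise SD, signal units (>= 0).
#' @param slope calibration slope, signal units per analyte unit (> 0).
#' @return LOD in analyte units.
#' @examples
#' compute_lod(0.39 * 0.1122 / 3.3, 0.1122)  # 0.39 mM
#' @export
compute_lod <- function(sigma, slope) {
  if (slope <= 0) stop("`slope` must be strictly positive", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  3.3 * sigma / slope
}

#' Invert a calibration curve
#'
#' Algebraic inverse of the fitted model: concentration recovered from a
#' readout. Readouts mapping outside the calibrated range are returned
#' as-is but flagged (`out_of_range` attribute and a warning), never
#' silently clamped.
#'
#' @param curve a [calibration_curve].
#' @param readout signal value(s) in the curve's signal units.
#' @return concentration(s) in analyte units, with logical attribute
#'   `out_of_range`.
#' @examples
#' cv <- fit_amperometric(0:10, 2 * (0:10))
#' inverse_concentration(cv, 4)  # 2
#' @export
inverse_concentration <- function(curve, readout) {
  stopifnot(inherits(curve, "calibration_curve"))
  # the fitted model is always y = intercept + slope * x; for ion channels
  # x = log10(conc / ref_conc), otherwise x is the concentration (or pH,
  # with a negative fitted slope under the default sign convention)
  conc <- if (curve$modality == "potentiometric") {
    curve$ref_conc * 10^((readout - curve$intercept) / curve$slope)
  } else {
    (readout - curve$intercept) / curve$slope
  }
  oor <- conc < curve$range[1] | conc > curve$range[2]
  if (any(oor)) {
    warning(sum(oor), " readout(s) map outside the calibrated range [",
            curve$range[1], ", ", curve$range[2], "]", call. = FALSE)
  }
  attr(conc, "out_of_range") <- oor
  conc
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> ", x$channel, " [", x$modality, "]\n", sep = "")
  cat(sprintf("  slope %.6g, intercept %.6g, r %.4f, sigma %.4g, LOD %.4g\n",
              x$slope, x$intercept, x$r, x$sigma, x$lod))
  cat("  range [", x$range[1], ", ", x$range[2], "]\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    channel = x$channel, modality = x$modality, slope = x$slope,
    intercept = x$intercept, r = x$r, sigma = x$sigma, lod = x$lod,
    range_lo = x$range[1], range_hi = x$range[2]
  )
}

#' Serialize calibration curves to JSON
#'
#' @param curves a `calibration_curve` or list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(curves, path) {
  if (inherits(curves, "calibration_curve")) curves <- list(curves)
  payload <- lapply(curves, function(cv) {
    list(channel = cv$channel, modality = cv$modality, slope = cv$slope,
         intercept = cv$intercept, r = cv$r, sigma = cv$sigma,
         lod = cv$lod, range = cv$range, ref_conc = cv$ref_conc)
  })
  names(payload) <- vapply(curves, `[[`, "", "channel")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Fit all six channels through the sensor twin
#'
#' Convenience round trip: for each channel, generate a concentration
#' ladder through the forward model, take steady-state readouts, and fit
#' the matching calibration model. With `noiseless = TRUE` the recovered
#' slopes equal the generating sensitivities to numerical precision.
#'
#' @param params named list of [channel_params()] (default the device
#'   parameterisation).
#' @param n_points ladder points per amperometric channel.
#' @param noiseless generate without noise/drift.
#' @param seed seed for noisy ladders.
#' @return named list of [calibration_curve] objects.
#' @export
calibrate_all_channels <- function(params = default_channel_params(),
                                   n_points = 11, noiseless = TRUE,
                                   seed = 1L) {
  if (noiseless) {
    params <- lapply(params, function(p) { p$noise_sd <- 0; p$drift_rate <- 0; p })
  }
  out <- list()
  for (ch in names(params)) {
    p <- params[[ch]]
    if (p$modality == "amperometric") {
      conc <- seq(p$linear_range[1], p$linear_range[2],
                  length.out = n_points)
    } else if (p$modality == "potentiometric") {
      n_doub <- floor(log2(p$linear_range[2] / p$linear_range[1]))
      conc <- p$linear_range[1] * 2^(0:n_doub)
    } else {
      conc <- seq(p$linear_range[1], p$linear_range[2], by = 1)
    }
    readout <- vapply(seq_along(conc), function(i) {
      tr <- if (p$modality == "amperometric") {
        amperometric_forward(conc[i], p, duration_s = 60,
                             seed = child_seed(seed, i))
      } else {
        potentiometric_forward(conc[i], p, duration_s = 60,
                               seed = child_seed(seed, i))
      }
      steady_state(tr, window_s = 30)
    }, numeric(1))
    out[[ch]] <- if (p$modality == "amperometric") {
      fit_amperometric(conc, readout, channel = ch)
    } else {
      fit_potentiometric(conc, readout,
                         modality = if (p$modality == "ph") "ph"
                                    else "potentiometric",
                         channel = ch, ref_conc = p$ref_conc)
    }
  }
  out
}

#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  xs <- seq(object$range[1], object$range[2], length.out = 50)
  reg <- switch(object$modality,
    amperometric = xs,
    potentiometric = log10(xs / object$ref_conc),
    ph = xs
  )
  df <- tibble::tibble(conc = xs,
                       y = object$intercept + object$slope * reg)
  xlab <- switch(object$modality,
    amperometric = "concentration",
    potentiometric = "concentration (log scale)",
    ph = "pH"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$y)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::labs(x = xlab, y = "fitted signal",
                  title = sprintf("%s: slope %.4g, r = %.3f",
                                  object$channel, object$slope, object$r)) +
    ggplot2::theme_minimal()
  if (object$modality == "potentiometric") p <- p + ggplot2::scale_x_log10()
  p
}
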