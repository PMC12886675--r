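#' Acute intervention protocol
#'
#' Defines a one-hour acute challenge: `"HG"` (hyperglycemia: a glucose
#' pulse that peaks about 20 min after administration and returns to
#' baseline within about 30 min), `"HUA"` (hyperuricemia: uric acid stable
#' for the first ~15 min, then a sigmoidal rise from ~160.2 to ~1015 uM
#' followed by a sustained plateau), or `"NORM"` (sham: all channels are
#' stationary noise about their baselines).
#'
#' @param kind `"NORM"`, `"HG"` or `"HUA"`.
#' @param baseline_level,peak_level target-analyte baseline and peak, in
#'   the analyte's units. Defaults: glucose 5.5 -> 15 mM (HG), uric acid
#'   160.2 -> 1015 uM (HUA).
#' @param onset_min minutes until the challenge response starts.
#' @param peak_time_min minutes at which the target peaks (HG) or the
#'   plateau is reached (HUA).
#' @param return_time_min minutes after the peak within which the HG pulse
#'   returns to baseline.
#' @param duration_min total monitoring duration.
#' @param dt_s sampling interval in seconds (must be > 0).
#' @param noise_frac per-channel Gaussian noise SD as a fraction of the
#'   channel baseline (pH uses an absolute 0.02 SD).
#' @return an object of class `intervention_protocol`.
#' @export
intervention_protocol <- function(kind = c("NORM", "HG", "HUA"),
                                  baseline_level = NULL,
                                  peak_level = NULL,
                                  onset_min = NULL,
                                  peak_time_min = NULL,
                                  return_time_min = 30,
                                  duration_min = 60,
                                  dt_s = 10,
                                  noise_frac = 0.01) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    NORM = list(baseline = NA_real_, peak = NA_real_, onset = NA_real_,
                peak_time = NA_real_),
    HG = list(baseline = 5.5, peak = 15, onset = 5, peak_time = 20),
    HUA = list(baseline = 160.2, peak = 1015, onset = 15, peak_time = 25)
  )
  baseline_level <- baseline_level %||% defaults$baseline
  peak_level <- peak_level %||% defaults$peak
  onset_min <- onset_min %||% defaults$onset
  peak_time_min <- peak_time_min %||% defaults$peak_time
  if (dt_s <= 0) stop("`dt_s` must be positive", call. = FALSE)
  if (kind != "NORM") {
    if (onset_min >= peak_time_min) {
      stop("`onset_min` must precede `peak_time_min`", call. = FALSE)
    }
    # the challenged channel may overshoot the calibrated ladder slightly
    # (the high-UA challenge drives uric acid just past the 1000 uM top of
    # range); allow 10% headroom above the calibrated upper bound
    rng <- sensor_ranges()[[if (kind == "HG") "glucose" else "ua"]]
    lv <- c(baseline_level, peak_level)
    if (any(lv < rng[1] | lv > 1.1 * rng[2])) {
      stop("baseline/peak levels must lie within [", rng[1], ", ",
           1.1 * rng[2], "] (calibrated range plus 10% headroom)",
           call. = FALSE)
    }
  }
  if (kind == "HG" && duration_min < peak_time_min + return_time_min) {
    stop("`duration_min` must cover the pulse return (>= peak_time_min + ",
         "return_time_min)", call. = FALSE)
  }
  structure(
    list(kind = kind, baseline_level = baseline_level,
         peak_level = peak_level, onset_min = onset_min,
         peak_time_min = peak_time_min, return_time_min = return_time_min,
         duration_min = duration_min, dt_s = dt_s,
         noise_frac = noise_frac),
    class = "intervention_protocol"
  )
}

# HG pulse shape: gamma-like, 0 at onset, 1 at peak_time, decayed to <3%
# of the peak one return_time after the peak (shape parameter 4)
hg_pulse <- function(t_min, onset, peak_time) {
  tau <- (t_min - onset) / (peak_time - onset)
  out <- numeric(length(t_min))
  pos <- tau > 0
  a <- 4
  out[pos] <- tau[pos]^a * exp(a * (1 - tau[pos]))
  out
}

# HUA rise: logistic with midpoint halfway between onset and plateau time,
# scale 1/10 of the rise interval, so the pre-onset leakage is negligible
hua_rise <- function(t_min, onset, peak_time) {
  mid <- (onset + peak_time) / 2
  scl <- (peak_time - onset) / 10
  1 / (1 + exp(-(t_min - mid) / scl))
}

#' Simulate an acute intervention
#'
#' Generates a time-indexed biomarker panel table over the monitoring
#' period. The targeted channel follows the protocol's trajectory (smooth
#' gamma-like pulse for HG; logistic rise-and-plateau for HUA); all other
#' channels are stationary Gaussian noise about the default cohort
#' baselines.
#'
#' @param protocol an [intervention_protocol()].
#' @param seed integer seed.
#' @return a tibble with the panel columns of [simulate_chronic()], `week`
#'   `NA`, `time_min` running from 0 to `duration_min`, and `group` set to
#'   the protocol kind.
#' @examples
#' hg <- simulate_acute(intervention_protocol("HG"), seed = 1)
#' hg$time_min[which.max(hg$glucose_mM)]  # ~ 20 min
#' @export
simulate_acute <- function(protocol, seed = 1L) {
  stopifnot(inherits(protocol, "intervention_protocol"))
  base <- c(glucose = 5.5, ua = 160.2, cholesterol = 4.0, na = 140,
            k = 4.2, ph = 7.1)
  if (protocol$kind == "HG") base[["glucose"]] <- protocol$baseline_level
  if (protocol$kind == "HUA") base[["ua"]] <- protocol$baseline_level
  t_min <- seq(0, protocol$duration_min, by = protocol$dt_s / 60)
  n <- length(t_min)
  rng <- sensor_ranges()

  with_seed(seed, {
    vals <- lapply(analyte_channels(), function(ch) {
      sd_ch <- if (ch == "ph") 0.02 else protocol$noise_frac * base[[ch]]
      mu <- rep(base[[ch]], n)
      if (protocol$kind == "HG" && ch == "glucose") {
        mu <- mu + (protocol$peak_level - protocol$baseline_level) *
          hg_pulse(t_min, protocol$onset_min, protocol$peak_time_min)
      }
      if (protocol$kind == "HUA" && ch == "ua") {
        mu <- mu + (protocol$peak_level - protocol$baseline_level) *
          hua_rise(t_min, protocol$onset_min, protocol$peak_time_min)
      }
      target <- (protocol$kind == "HG" && ch == "glucose") ||
        (protocol$kind == "HUA" && ch == "ua")
      hi <- if (target) 1.1 * rng[[ch]][2] else rng[[ch]][2]
      pmin(pmax(mu + rnorm(n, 0, sd_ch), rng[[ch]][1]), hi)
    })
    names(vals) <- analyte_channels()
    tibble::tibble(
      sample_id = sprintf("%s_t%04d", protocol$kind, seq_len(n) - 1L),
      group = protocol$kind, week = NA_integer_, time_min = t_min,
      glucose_mM = vals$glucose, ua_uM = vals$ua,
      cholesterol_mM = vals$cholesterol, na_mM = vals$na, k_mM = vals$k,
      ph = vals$ph, degree = 0, subject_id = protocol$kind
    )
  })
}
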