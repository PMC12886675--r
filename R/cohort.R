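#' Chronic cohort configuration
#'
#' Configuration of the simulated chronic diet study: three groups (CON,
#' a control on standard chow; HFFD, a high-fat-high-fructose diet; HFFSD,
#' the same diet with added salt), each measured weekly. Baseline means must
#' lie inside the physiological ranges of the six analytes (glucose 4.4-6.6
#' mM, uric acid 130-460 uM, cholesterol 2.9-5.2 mM, Na+ 135-145 mM, K+
#' 3.5-5 mM, pH 6.6-7.6). Group effects grow linearly with week at the
#' per-week rates in `effect_rates`; the defaults raise glucose, cholesterol
#' and uric acid in both diet groups (more strongly in HFFSD), with an
#' additional Na+ rise and slight acidification in HFFSD reflecting the
#' salt load. The defaults are sized so that post-baseline weeks are
#' near-separable between groups.
#'
#' @param n_per_group animals per group (default 3, the study's cohort
#'   size).
#' @param weeks number of post-baseline weeks (default 4); panels are
#'   emitted for weeks `0:weeks`.
#' @param baseline_means,baseline_sds named 6-vectors (channels
#'   `glucose, ua, cholesterol, na, k, ph`) of baseline means and
#'   measurement-level SDs, in analyte units.
#' @param effect_rates named list mapping each group to a named 6-vector of
#'   per-week mean shifts (analyte units per week).
#' @param glucose_cholesterol_rho latent correlation between the glucose and
#'   cholesterol deviations, applied at both the animal and the measurement
#'   level so the marginal correlation equals `rho`.
#' @param animal_sd_frac SD of the animal-level random intercept, as a
#'   fraction of `baseline_sds` (repeated measures on one animal are
#'   correlated).
#' @param s_max named vector of maximal health degrees reached at the final
#'   week by each group (linear ramp from 0).
#' @param degree_noise_sd SD of the Gaussian noise added to the health
#'   degree label before clipping to [0, 1].
#' @param seed integer seed for [simulate_chronic()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 3,
                          weeks = 4,
                          baseline_means = c(glucose = 5.5, ua = 295,
                                             cholesterol = 4.0, na = 140,
                                             k = 4.2, ph = 7.1),
                          baseline_sds = c(glucose = 0.25, ua = 25,
                                           cholesterol = 0.2, na = 1.2,
                                           k = 0.25, ph = 0.06),
                          effect_rates = default_effect_rates(),
                          glucose_cholesterol_rho = 0.6,
                          animal_sd_frac = 0.5,
                          s_max = c(CON = 0, HFFD = 0.7, HFFSD = 1.0),
                          degree_noise_sd = 0.02,
                          seed = 1L) {
  chans <- analyte_channels()
  stopifnot(n_per_group >= 1, weeks >= 0)
  if (abs(glucose_cholesterol_rho) > 1) {
    stop("|glucose_cholesterol_rho| must be <= 1", call. = FALSE)
  }
  baseline_means <- baseline_means[chans]
  baseline_sds <- baseline_sds[chans]
  if (anyNA(baseline_means) || anyNA(baseline_sds)) {
    stop("baseline means/SDs must name all six channels", call. = FALSE)
  }
  phys <- physiological_ranges()
  bad <- phys$channel[baseline_means < phys$lo | baseline_means > phys$hi]
  if (length(bad)) {
    stop("baseline mean outside the physiological range for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (g in names(effect_rates)) {
    effect_rates[[g]] <- effect_rates[[g]][chans]
    effect_rates[[g]][is.na(effect_rates[[g]])] <- 0
    names(effect_rates[[g]]) <- chans
  }
  # group means must stay inside the sensor linear ranges at every week
  rng <- sensor_ranges()
  for (g in names(effect_rates)) {
    mu <- baseline_means + effect_rates[[g]] * weeks
    for (ch in chans) {
      if (mu[ch] < rng[[ch]][1] || mu[ch] > rng[[ch]][2]) {
        stop("effect shift pushes the ", g, " group mean of channel `", ch,
             "` outside the sensor range at week ", weeks, call. = FALSE)
      }
    }
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group), weeks = as.integer(weeks),
      baseline_means = baseline_means, baseline_sds = baseline_sds,
      effect_rates = effect_rates,
      glucose_cholesterol_rho = glucose_cholesterol_rho,
      animal_sd_frac = animal_sd_frac, s_max = s_max,
      degree_noise_sd = degree_noise_sd, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Default per-week group effects
#'
#' Per-week mean shifts of the three diet groups. Both diet groups raise
#' glucose, cholesterol and uric acid (cholesterol similarly in both, so it
#' separates control from diet; glucose about twice as fast in HFFSD, so it
#' separates the two diets); HFFSD additionally raises Na+ and lowers pH,
#' reflecting its salt content. K+ carries no diet effect.
#'
#' @return named list of named 6-vectors (analyte units per week).
#' @export
default_effect_rates <- function() {
  list(
    CON = c(glucose = 0, ua = 0, cholesterol = 0, na = 0, k = 0, ph = 0),
    HFFD = c(glucose = 1.5, ua = 70, cholesterol = 1.0, na = 0, k = 0,
             ph = 0),
    HFFSD = c(glucose = 3.2, ua = 100, cholesterol = 1.2, na = 4.0, k = 0,
              ph = -0.12)
  )
}

#' Ground-truth health degree
#'
#' Deterministic latent severity underlying the regression labels: a linear
#' ramp from 0 at week 0 to the group's `s_max` at the final week. The
#' control group is the healthy reference and is 0 at every week; HFFSD
#' reaches a higher degree than HFFD at equal week under the defaults.
#'
#' @param group group name (must be a chronic group in `config$s_max`).
#' @param week integer week in `0:config$weeks`.
#' @param config a [cohort_config()].
#' @return health degree in [0, 1].
#' @examples
#' cfg <- cohort_config()
#' severity("HFFSD", 4, cfg)  # 1
#' severity("CON", 3, cfg)    # 0
#' @export
severity <- function(group, week, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!group %in% names(config$s_max)) {
    stop("unknown group `", group, "`; known groups: ",
         paste(names(config$s_max), collapse = ", "), call. = FALSE)
  }
  if (any(week < 0 | week > config$weeks)) {
    stop("`week` must lie in [0, ", config$weeks, "]", call. = FALSE)
  }
  if (config$weeks == 0) return(rep(0, length(week)))
  unname(config$s_max[[group]] * week / config$weeks)
}

#' Simulate the chronic cohort
#'
#' Draws one biomarker panel per animal per week for each of the three diet
#' groups. Each animal carries a random intercept (SD
#' `animal_sd_frac * baseline_sds`) shared across its weekly measurements;
#' glucose and cholesterol deviations share a latent Gaussian factor with
#' correlation `glucose_cholesterol_rho` at both the animal and measurement
#' level. The health-degree label is the deterministic [severity()] ramp
#' plus Gaussian noise (`degree_noise_sd`), clipped to [0, 1]. Analyte
#' values are clipped to the sensor linear ranges, mirroring physical
#' saturation; the number of clipped values is recorded in the `clipped`
#' attribute of the result.
#'
#' @param config a [cohort_config()].
#' @return a tibble with columns `sample_id, group, week, time_min,
#'   glucose_mM, ua_uM, cholesterol_mM, na_mM, k_mM, ph, degree,
#'   subject_id` and attribute `clipped` (count of range-clipped values).
#'   `time_min` is `NA` for chronic panels.
#' @examples
#' panels <- simulate_chronic(cohort_config(n_per_group = 10))
#' nrow(panels)  # 10 animals x 3 groups x 5 weeks = 150
#' @export
simulate_chronic <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  chans <- analyte_channels()
  groups <- names(config$effect_rates)
  rho <- config$glucose_cholesterol_rho
  rng <- sensor_ranges()

  with_seed(config$seed, {
    rows <- list()
    clipped <- 0L
    for (g in groups) {
      for (i in seq_len(config$n_per_group)) {
        subj <- sprintf("%s_a%02d", g, i)
        a_sd <- config$animal_sd_frac * config$baseline_sds
        intercept <- correlated_deviates(a_sd, rho)
        for (w in 0:config$weeks) {
          eps <- correlated_deviates(config$baseline_sds, rho)
          mu <- config$baseline_means + config$effect_rates[[g]] * w
          val <- mu + intercept + eps
          for (ch in chans) {
            lo <- rng[[ch]][1]; hi <- rng[[ch]][2]
            if (val[ch] < lo || val[ch] > hi) {
              clipped <- clipped + 1L
              val[ch] <- min(max(val[ch], lo), hi)
            }
          }
          deg <- severity(g, w, config) +
            rnorm(1, 0, config$degree_noise_sd)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = sprintf("%s_w%d", subj, w),
            group = g, week = w, time_min = NA_real_,
            glucose_mM = val[["glucose"]], ua_uM = val[["ua"]],
            cholesterol_mM = val[["cholesterol"]], na_mM = val[["na"]],
            k_mM = val[["k"]], ph = val[["ph"]],
            degree = min(max(deg, 0), 1), subject_id = subj
          )
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "clipped") <- clipped
    if (clipped > 0) {
      message(clipped, " analyte value(s) clipped to the sensor range")
    }
    out
  })
}

# 6-vector of zero-mean deviates with glucose-cholesterol correlation rho
correlated_deviates <- function(sds, rho) {
  z <- rnorm(6)
  names(z) <- analyte_channels()
  z[["cholesterol"]] <- rho * z[["glucose"]] +
    sqrt(1 - rho^2) * z[["cholesterol"]]
  z * sds
}

panel_value_cols <- function() {
  c("glucose_mM", "ua_uM", "cholesterol_mM", "na_mM", "k_mM", "ph")
}

#' Write / read biomarker panels as CSV with a JSON manifest
#'
#' `write_panels()` writes the panel table to CSV (standard header
#' `sample_id,group,week,time_min,glucose_mM,ua_uM,cholesterol_mM,na_mM,
#' k_mM,ph,degree,subject_id`) and a JSON sidecar `<path>.manifest.json`
#' recording the generating configuration and seed. `read_panels()` reads
#' the CSV back into the same tibble shape.
#'
#' @param panels panel tibble from [simulate_chronic()] or
#'   [simulate_acute()].
#' @param path CSV path.
#' @param config optional generating config recorded in the manifest.
#' @return `write_panels()` returns `path` invisibly; `read_panels()` the
#'   panel tibble.
#' @export
write_panels <- function(panels, path, config = NULL) {
  utils::write.csv(as.data.frame(panels), path, row.names = FALSE)
  manifest <- list(
    created = "run-time artifact",
    n_panels = nrow(panels),
    columns = names(panels),
    clipped = attr(panels, "clipped") %||% 0L
  )
  if (!is.null(config)) {
    manifest$config <- unclass(config)
  }
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panels
#' @export
read_panels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
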