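#' Oral glucose tolerance test blood-glucose time course
#'
#' Simulates the blood-glucose excursion of a 75 g oral glucose tolerance
#' test sampled on the reference-meter cadence: a flat baseline with a slow
#' random-walk drift before intake, then a Bateman rise-and-decay
#' (first-order absorption and elimination) peaking 30--60 minutes after
#' the drink.
#'
#' @param duration_min length of the experiment (minutes).
#' @param intake_min time of the glucose drink (minutes after the start of
#'   the measurements; the standard protocol uses 20).
#' @param baseline_mg_dl fasting glucose (mg/dl).
#' @param peak_rise_mg_dl excursion height above baseline at the peak
#'   (mg/dl).
#' @param cadence_min sampling interval of the invasive reference
#'   measurements (minutes).
#' @param t_absorb_min,t_elim_min Bateman absorption and elimination time
#'   constants (minutes); the defaults put the peak about 37 min after
#'   intake.
#' @param drift_sd_mg_dl sd of the per-sample random-walk drift (mg/dl).
#' @param seed optional RNG seed.
#' @return A `glucose_profile`: list with `times`, `values`,
#'   `intake_time`.
#' @export
ogtt_glucose_profile <- function(duration_min = 120,
                                 intake_min = 20,
                                 baseline_mg_dl = 90,
                                 peak_rise_mg_dl = 80,
                                 cadence_min = 5,
                                 t_absorb_min = 20,
                                 t_elim_min = 80,
                                 drift_sd_mg_dl = 1,
                                 seed = NULL) {
  if (baseline_mg_dl <= 0) stop("baseline glucose must be positive")
  if (intake_min >= duration_min) {
    stop("intake time must fall inside the experiment duration")
  }
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration_min, by = cadence_min)
  # Bateman response normalized to unit peak
  bateman <- function(u) {
    b <- ifelse(u > 0, exp(-u / t_elim_min) - exp(-u / t_absorb_min), 0)
    u_peak <- log(t_elim_min / t_absorb_min) * t_absorb_min * t_elim_min /
      (t_elim_min - t_absorb_min)
    b / (exp(-u_peak / t_elim_min) - exp(-u_peak / t_absorb_min))
  }
  drift <- cumsum(stats::rnorm(length(times), 0, drift_sd_mg_dl))
  values <- baseline_mg_dl + drift +
    peak_rise_mg_dl * bateman(times - intake_min)
  values <- pmax(values, 1)
  structure(list(times = times, values = values, intake_time = intake_min),
            class = "glucose_profile")
}

#' Reference blood-glucose meter error model
#'
#' A handheld meter reads `true * (1 + e)` with `e ~ Normal(0, sigma_rel)`.
#' The default `sigma_rel = 0.05` reproduces a meter with 68% of readings
#' within 5% of truth (and implies 95% within 10%).
#'
#' @param sigma_rel relative standard deviation of the meter error.
#' @return a `meter_model` list.
#' @export
meter_model <- function(sigma_rel = 0.05) {
  if (sigma_rel < 0) stop("sigma_rel must be non-negative")
  structure(list(sigma_rel = sigma_rel), class = "meter_model")
}

#' Draw reference-meter readings
#'
#' @param true_glucose true blood glucose (mg/dl), vectorized.
#' @param meter a [meter_model()].
#' @param seed optional RNG seed.
#' @return readings (mg/dl), same length as `true_glucose`.
#' @export
reference_meter_reading <- function(true_glucose, meter = meter_model(),
                                    seed = NULL) {
  if (any(true_glucose <= 0)) stop("true glucose must be positive")
  if (!is.null(seed)) set.seed(seed)
  true_glucose * (1 + stats::rnorm(length(true_glucose), 0, meter$sigma_rel))
}
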