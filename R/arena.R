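#' Lock arena geometry
#'
#' Describes the navigation-lock chamber as a rectangle in a local projected
#' frame: x runs along the lock axis from the upstream wall (x = 0) to the
#' downstream gate line, y across the chamber. The downstream gate segment at
#' \code{gate_x} is open; fish crossing it have exited. Defaults match the
#' study lock (51.82 m long, 11.12 m wide at the top).
#'
#' @param length chamber length in meters (> 0).
#' @param width chamber width in meters (> 0).
#' @param gate_x x-coordinate of the open gate line in meters, in
#'   \code{[0, length]}. Defaults to the downstream end.
#' @return an object of class \code{lock_arena}.
#' @examples
#' lock_arena()
#' @export
lock_arena <- function(length = 51.82, width = 11.12, gate_x = length) {
  if (!is_scalar_number(length) || length <= 0)
    abort("`length` must be a positive number (meters)", "carplock_invalid_arena")
  if (!is_scalar_number(width) || width <= 0)
    abort("`width` must be a positive number (meters)", "carplock_invalid_arena")
  if (!is_scalar_number(gate_x) || gate_x < 0 || gate_x > length)
    abort("`gate_x` must lie in [0, length]", "carplock_invalid_arena")
  structure(list(length = length, width = width, gate_x = gate_x),
            class = "lock_arena")
}

#' @export
print.lock_arena <- function(x, ...) {
  cat(sprintf("Lock arena: %.2f m x %.2f m, gate line at x = %.2f m\n",
              x$length, x$width, x$gate_x))
  invisible(x)
}

TREATMENT_LABELS <- c("null", "pump_only", "pump_co2")

#' Build a treatment covariate profile for one trial
#'
#' Encodes the deterrent schedule of a trial as functions of time since gate
#' opening. Under \code{pump_only} and \code{pump_co2} the circulation pumps
#' are on from t = 0; under \code{pump_co2} the dissolved CO2 concentration
#' ramps linearly from 0 to \code{target_co2} over \code{ramp_minutes} and is
#' then held. Under \code{null} both pump and CO2 stay at zero. Water
#' temperature is constant within a trial.
#'
#' @param label one of \code{"null"}, \code{"pump_only"}, \code{"pump_co2"}.
#' @param horizon_s trial duration in seconds (> 0); default 90 minutes.
#' @param ramp_minutes minutes taken to reach the CO2 target (5-10 in the
#'   study design).
#' @param target_co2 plateau CO2 concentration in mg/L (100-150 in the study
#'   design).
#' @param temperature trial water temperature in degrees Celsius.
#' @return an object of class \code{treatment_profile} with elements
#'   \code{pump_on(t)} and \code{co2_mgL(t)} (vectorized functions of seconds
#'   since gate opening), \code{temperature_C}, \code{horizon_s} and
#'   \code{label}.
#' @examples
#' pr <- make_treatment_profile("pump_co2", target_co2 = 150, ramp_minutes = 10)
#' pr$co2_mgL(600)  # 150 at the end of the ramp
#' @export
make_treatment_profile <- function(label,
                                   horizon_s = 90 * 60,
                                   ramp_minutes = 7.5,
                                   target_co2 = 125,
                                   temperature = 22) {
  if (!is.character(label) || length(label) != 1L || !label %in% TREATMENT_LABELS)
    abort(sprintf("unknown treatment label %s; must be one of %s",
                  deparse(label), paste(TREATMENT_LABELS, collapse = ", ")),
          "carplock_unknown_treatment")
  if (!is_scalar_number(horizon_s) || horizon_s <= 0)
    abort("`horizon_s` must be a positive number of seconds", "carplock_invalid_profile")
  if (!is_scalar_number(ramp_minutes) || ramp_minutes <= 0)
    abort("`ramp_minutes` must be positive", "carplock_invalid_profile")
  if (!is_scalar_number(target_co2) || target_co2 < 0)
    abort("`target_co2` must be nonnegative (mg/L)", "carplock_invalid_profile")
  if (!is_scalar_number(temperature))
    abort("`temperature` must be a finite number (degrees C)", "carplock_invalid_profile")

  pump <- if (label == "null") {
    function(t) rep(0, length(t))
  } else {
    function(t) as.numeric(t >= 0)
  }
  co2 <- if (label == "pump_co2") {
    ramp_s <- ramp_minutes * 60
    function(t) pmax(0, pmin(t / ramp_s, 1)) * target_co2
  } else {
    function(t) rep(0, length(t))
  }

  structure(list(
    label = label,
    pump_on = pump,
    co2_mgL = co2,
    temperature_C = temperature,
    horizon_s = horizon_s,
    ramp_minutes = if (label == "pump_co2") ramp_minutes else NA_real_,
    target_co2 = if (label == "pump_co2") target_co2 else 0
  ), class = "treatment_profile")
}

#' @export
print.treatment_profile <- function(x, ...) {
  cat(sprintf("Treatment profile '%s': horizon %.0f s, %.1f C", x$label,
              x$horizon_s, x$temperature_C))
  if (x$label == "pump_co2")
    cat(sprintf(", CO2 ramp to %.0f mg/L over %.1f min", x$target_co2,
                x$ramp_minutes))
  cat("\n")
  invisible(x)
}

#' Evaluate a treatment profile on a time grid
#'
#' @param profile a \code{treatment_profile}.
#' @param trial_id identifier recorded in the output.
#' @param dt_s grid spacing in seconds.
#' @return data.frame with columns \code{trial_id}, \code{t_s},
#'   \code{pump_on}, \code{co2_mgL}, \code{temp_C}.
#' @export
covariate_series <- function(profile, trial_id, dt_s = 6) {
  stopifnot(inherits(profile, "treatment_profile"))
  t <- seq(0, profile$horizon_s, by = dt_s)
  data.frame(trial_id = trial_id, t_s = t,
             pump_on = profile$pump_on(t),
             co2_mgL = profile$co2_mgL(t),
             temp_C = rep(profile$temperature_C, length(t)))
}

#' Trial roster of the experimental design
#'
#' The 20-trial roster of the study: 11 CO2-with-circulation trials, 7
#' circulation-only trials and 2 null trials, with 2-3 tagged carp stocked per
#' trial. Trial water temperatures are not reported per trial; defaults vary
#' mildly around a late-summer river temperature of 22 C so the temperature
#' covariate is not degenerate.
#'
#' @return data.frame with columns \code{trial_id}, \code{treatment},
#'   \code{n_fish}, \code{temp_C}.
#' @export
study_roster <- function() {
  trial_id <- c(1, 3, 5, 7, 8, 9, 11, 13, 15, 16, 18, 20, 22, 23, 25, 27, 29,
                30, 32, 34)
  treatment <- c("pump_co2", "pump_co2", "pump_only", "pump_only", "pump_co2",
                 "pump_co2", "pump_only", "pump_co2", "null", "pump_co2",
                 "pump_only", "pump_only", "pump_co2", "pump_co2", "pump_only",
                 "pump_co2", "null", "pump_co2", "pump_co2", "pump_co2")
  n_fish <- c(3, 3, 3, 3, 3, 2, 3, 3, 3, 3, 2, 3, 3, 3, 3, 3, 3, 3, 3, 2)
  # deterministic spread of trial temperatures, 20.5-23.5 C
  temp_C <- 22 + 1.5 * sin(seq_along(trial_id))
  data.frame(trial_id = trial_id, treatment = treatment, n_fish = n_fish,
             temp_C = round(temp_C, 2))
}
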