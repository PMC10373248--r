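#' Step lengths and turning angles from a regular track
#'
#' Converts a 6-s regular track into the HMM's observation series: step k is
#' the Euclidean distance between positions k and k+1; the turning angle at
#' step k is the signed change between the bearing of step k-1 and step k,
#' wrapped to (-pi, pi], positive for left (counter-clockwise) turns. The
#' angle is missing for the first step of a track and wherever an adjacent
#' step has zero length (bearing undefined). Covariates are joined by nearest
#' time at each step's start.
#'
#' @param track data.frame with \code{t_s}, \code{x_m}, \code{y_m} and
#'   optionally \code{fish_id}; at least 2 positions (3 for any angle).
#' @param covariates data.frame with \code{t_s}, \code{pump_on},
#'   \code{co2_mgL}, \code{temp_C} and optionally \code{trial_id}, covering
#'   the track's time span.
#' @return data.frame (class \code{step_angle_series}) with columns
#'   \code{fish_id}, \code{trial_id}, \code{step_index}, \code{t_s} (step
#'   start), \code{step_m}, \code{angle_rad}, \code{pump_on}, \code{co2_mgL},
#'   \code{temp_C}.
#' @examples
#' trk <- data.frame(t_s = c(0, 6, 12), x_m = c(0, 1, 1), y_m = c(0, 0, 1))
#' cov <- data.frame(t_s = c(0, 12), pump_on = 0, co2_mgL = 0, temp_C = 20)
#' steps_and_angles(trk, cov)  # angle +pi/2: left turn
#' @export
steps_and_angles <- function(track, covariates) {
  req <- c("t_s", "x_m", "y_m")
  if (!all(req %in% names(track)))
    abort("track must have columns t_s, x_m, y_m", "carplock_invalid_data")
  n <- nrow(track)
  if (n < 2L)
    abort("track needs at least 2 positions to form a step", "carplock_invalid_data")
  creq <- c("t_s", "pump_on", "co2_mgL", "temp_C")
  if (!all(creq %in% names(covariates)))
    abort("covariates must have columns t_s, pump_on, co2_mgL, temp_C",
          "carplock_invalid_data")
  if (min(covariates$t_s) > min(track$t_s) + 1e-9 ||
      max(covariates$t_s) < max(track$t_s[-n]) - 1e-9)
    abort("covariate table does not cover the track's time span",
          "carplock_covariate_span")

  dx <- diff(track$x_m); dy <- diff(track$y_m)
  step <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx)
  angle <- c(NA_real_, wrap_angle(diff(bearing)))
  zero <- step == 0
  # bearing undefined at zero-length steps: blank the angle on both sides
  angle[zero] <- NA_real_
  angle[c(FALSE, zero[-length(zero)])] <- NA_real_

  t_start <- track$t_s[-n]
  ct <- covariates$t_s
  i <- findInterval(t_start, ct, all.inside = TRUE)
  nearer <- abs(ct[pmin(i + 1, length(ct))] - t_start) < abs(ct[i] - t_start)
  i <- ifelse(nearer, pmin(i + 1, length(ct)), i)

  out <- data.frame(
    fish_id = if (!is.null(track$fish_id)) track$fish_id[-n] else "fish1",
    trial_id = if (!is.null(covariates$trial_id)) covariates$trial_id[i]
               else if (!is.null(track$trial_id)) track$trial_id[-n] else 1L,
    step_index = seq_len(n - 1L),
    t_s = t_start,
    step_m = step,
    angle_rad = angle,
    pump_on = covariates$pump_on[i],
    co2_mgL = covariates$co2_mgL[i],
    temp_C = covariates$temp_C[i]
  )
  class(out) <- c("step_angle_series", "data.frame")
  out
}
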