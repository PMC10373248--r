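#' Detect the lock-exit event on a regular track
#'
#' The exit time is the first time the track's x-coordinate reaches the gate
#' line, linearly interpolated between the bracketing grid positions; tracks
#' that never reach it are right-censored at the trial horizon.
#'
#' @param track data.frame with \code{t_s}, \code{x_m} (and optionally
#'   \code{fish_id}, \code{trial_id}).
#' @param arena a [lock_arena()].
#' @param horizon_min censoring horizon in minutes from the track start.
#' @param treatment optional treatment label carried into the record.
#' @return one-row data.frame (an exit record): \code{fish_id},
#'   \code{trial_id}, \code{treatment}, \code{time_min}, \code{event}.
#' @export
detect_exit <- function(track, arena, horizon_min = 90, treatment = NA_character_) {
  stopifnot(inherits(arena, "lock_arena"))
  if (!all(c("t_s", "x_m") %in% names(track)))
    abort("track must have columns t_s, x_m", "carplock_invalid_data")
  if (nrow(track) < 1L)
    abort("empty track", "carplock_invalid_data")
  x <- track$x_m; t <- track$t_s
  if (x[1] >= arena$gate_x)
    abort("track starts at or beyond the gate line", "carplock_invalid_data")
  t0 <- t[1]
  i <- which(x >= arena$gate_x)[1]
  if (is.na(i)) {
    time_min <- horizon_min; event <- 0L
  } else if (x[i] == arena$gate_x) {
    time_min <- (t[i] - t0) / 60; event <- 1L
  } else {
    f <- (arena$gate_x - x[i - 1]) / (x[i] - x[i - 1])
    time_min <- (t[i - 1] + f * (t[i] - t[i - 1]) - t0) / 60
    event <- 1L
  }
  if (event == 1L && time_min > horizon_min) {
    time_min <- horizon_min; event <- 0L
  }
  data.frame(
    fish_id = track$fish_id[1] %||% "fish1",
    trial_id = track$trial_id[1] %||% NA,
    treatment = treatment,
    time_min = time_min, event = event
  )
}

#' Kaplan-Meier estimate of time-to-exit
#'
#' Product-limit estimator with Greenwood standard errors, computed with
#' \pkg{survival}. "Survival" here means still inside the lock; censored
#' records (fish that never exited) reduce the risk set without an event.
#' Events precede censorings at tied times (the standard convention).
#'
#' @param records data.frame of exit records with columns \code{time_min}
#'   (> 0) and \code{event} (1 = exited, 0 = censored).
#' @return object of class \code{km_estimate}: \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{survival}, \code{greenwood_se}
#'   (all aligned vectors over the observed distinct times) and
#'   \code{median_exit_min}, the first time at which survival drops to 0.5
#'   or below (NA if it never does).
#' @examples
#' km_estimate(data.frame(time_min = c(1, 2, 3), event = 1))
#' @export
km_estimate <- function(records) {
  if (!all(c("time_min", "event") %in% names(records)) || nrow(records) == 0L)
    abort("records must be nonempty with columns time_min, event",
          "carplock_invalid_data")
  if (any(records$time_min <= 0 | is.na(records$time_min)))
    abort("exit times must be positive", "carplock_invalid_data")
  fit <- survival::survfit(survival::Surv(time_min, event) ~ 1,
                           data = records, conf.type = "plain")
  S <- fit$surv
  med <- fit$time[which(S <= 0.5)[1]]
  structure(list(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = S,
    # survfit std.err is on the log scale; S = 0 gives 0 * Inf, set to 0
    greenwood_se = ifelse(S == 0, 0, fit$std.err * S),
    median_exit_min = if (length(med) && !is.na(med)) med else NA_real_,
    n = fit$n
  ), class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier time-to-exit: n = %d, %d events; median %.1f min\n",
              x$n, sum(x$n_event), x$median_exit_min))
  invisible(x)
}

#' Median time-to-exit with censored fish set to the horizon
#'
#' The study's summary convention: the sample median of exit times after
#' assigning every censored fish the trial horizon. The Kaplan-Meier median
#' (first time survival falls to 0.5 or below) is returned alongside.
#'
#' @param records exit-record data.frame (\code{time_min}, \code{event}).
#' @param horizon_min trial horizon in minutes.
#' @return list with \code{median_min} (sample median, horizon convention)
#'   and \code{km_median_min}.
#' @export
median_exit <- function(records, horizon_min = 90) {
  if (nrow(records) == 0L)
    abort("no exit records", "carplock_invalid_data")
  tt <- ifelse(records$event == 1, records$time_min, horizon_min)
  list(median_min = median(tt),
       km_median_min = km_estimate(records)$median_exit_min)
}

#' Proportion of fish remaining with binomial standard error
#'
#' @param n_remaining number of fish still in the lock at the horizon.
#' @param n_start number of fish at the start (>= 1).
#' @return list with \code{p_percent} and \code{se_percent}, both on the
#'   percentage scale: p = 100 r/n, SE = 100 sqrt(p(1-p)/n) with p on the
#'   0-1 scale.
#' @examples
#' remaining_proportion(5, 34)  # 14.7% +/- 6.07%
#' @export
remaining_proportion <- function(n_remaining, n_start) {
  if (!is_scalar_number(n_start) || n_start < 1)
    abort("`n_start` must be >= 1", "carplock_invalid_data")
  if (!is_scalar_number(n_remaining) || n_remaining < 0 || n_remaining > n_start)
    abort("`n_remaining` must be in [0, n_start]", "carplock_invalid_data")
  p <- n_remaining / n_start
  list(p_percent = 100 * p, se_percent = 100 * sqrt(p * (1 - p) / n_start))
}
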