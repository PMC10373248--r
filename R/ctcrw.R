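#' Continuous-time correlated random walk (integrated OU) tools
#'
#' The track-regularization model treats each coordinate axis as an
#' integrated Ornstein-Uhlenbeck process: velocity mean-reverts to zero at
#' rate \code{beta_vel} (1/s) and is driven by white noise of intensity
#' \code{sigma_vel} (m/s per sqrt(s)); position is the time integral;
#' observed fixes add isotropic Gaussian measurement error with SD
#' \code{tau_obs} (m). Both axes share the same parameters. Exact
#' discrete-time transition moments over each inter-fix gap feed a Kalman
#' filter (likelihood) and an RTS smoother (regular-grid prediction).
#'
#' @name ctcrw
NULL

# exact transition moments of the integrated OU state (position, velocity)
# over a gap of dt seconds
iou_moments <- function(beta, sigma2, dt) {
  e <- exp(-beta * dt)
  phi <- (1 - e) / beta
  list(
    e = e, phi = phi,
    q11 = sigma2 / beta^2 * (dt - 2 * phi + (1 - e^2) / (2 * beta)),
    q12 = sigma2 / (2 * beta^2) * (1 - e)^2,
    q22 = sigma2 * (1 - e^2) / (2 * beta)
  )
}

validate_fixes <- function(fixes, min_n = 4L) {
  req <- c("t_s", "x_m", "y_m")
  if (!all(req %in% names(fixes)))
    abort("fixes must have columns t_s, x_m, y_m", "carplock_invalid_data")
  if (nrow(fixes) < min_n)
    abort(sprintf("at least %d fixes are required (got %d)", min_n, nrow(fixes)),
          "carplock_too_few_fixes")
  if (anyNA(fixes[req]))
    abort("fixes contain missing coordinates or times", "carplock_invalid_data")
  if (any(diff(fixes$t_s) <= 0))
    abort("fix times must be strictly increasing", "carplock_invalid_data")
  invisible(fixes)
}

#' Fit the CTCRW model to irregular fixes
#'
#' Maximum-likelihood estimation of (\code{beta_vel}, \code{sigma_vel},
#' \code{tau_obs}) by quasi-Newton optimization of the exact Kalman-filter
#' likelihood on the log-parameter scale, with deterministic multi-start to
#' guard against local optima.
#'
#' @param fixes data.frame with columns \code{t_s} (strictly increasing
#'   seconds), \code{x_m}, \code{y_m}; at least 4 fixes (10+ recommended).
#' @param init optional named list/vector with starting values
#'   \code{beta_vel}, \code{sigma_vel}, \code{tau_obs} (all > 0).
#' @return an object of class \code{ctcrw_fit}: the three parameters plus
#'   \code{loglik}, \code{convergence} (TRUE if the best start converged) and
#'   \code{n_fixes}.
#' @examples
#' trk <- simulate_ctcrw(200, beta_vel = 0.5, sigma_vel = 0.4,
#'                       tau_obs = 0.5, seed = 1)
#' fit_ctcrw(trk)
#' @export
fit_ctcrw <- function(fixes, init = NULL) {
  validate_fixes(fixes)
  dt <- diff(fixes$t_s)
  obs <- cbind(fixes$x_m, fixes$y_m)
  init_var <- 1e4

  if (is.null(init)) {
    # crude velocity scale from first differences
    v <- sqrt(diff(fixes$x_m)^2 + diff(fixes$y_m)^2) / dt
    init <- list(beta_vel = 0.5, sigma_vel = max(sd(v), 0.05), tau_obs = 0.5)
  }
  p0 <- log(c(init$beta_vel, init$sigma_vel, init$tau_obs))
  if (anyNA(p0) | any(!is.finite(p0[1:2])))
    abort("initial CTCRW values must be positive", "carplock_invalid_params")
  if (!is.finite(p0[3])) p0[3] <- log(1e-4)

  nll <- function(lp) {
    val <- ctcrw_negloglik_cpp(dt, obs, exp(lp[1]), exp(2 * lp[2]),
                               exp(2 * lp[3]), init_var)
    if (!is.finite(val)) 1e12 else val
  }

  # deterministic multi-start: heuristic start plus fixed offsets
  offsets <- list(c(0, 0, 0), c(1.2, -0.7, 0.7), c(-1.2, 0.7, -2))
  best <- NULL
  for (off in offsets) {
    opt <- tryCatch(
      optim(p0 + off, nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    abort("CTCRW optimization failed for all starts", "carplock_ctcrw_nonconvergence")
  fit <- structure(list(
    beta_vel = exp(best$par[1]),
    sigma_vel = exp(best$par[2]),
    tau_obs = exp(best$par[3]),
    loglik = -best$value,
    convergence = best$convergence == 0,
    n_fixes = nrow(fixes)
  ), class = "ctcrw_fit")
  if (!fit$convergence)
    abort("CTCRW optimization did not converge after restarts",
          "carplock_ctcrw_nonconvergence", best = fit)
  fit
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat(sprintf(paste0("CTCRW fit (%d fixes): beta_vel = %.4g /s, ",
                     "sigma_vel = %.4g, tau_obs = %.4g m, loglik = %.2f\n"),
              x$n_fixes, x$beta_vel, x$sigma_vel, x$tau_obs, x$loglik))
  invisible(x)
}

#' Simulate an irregular CTCRW track
#'
#' Draws from the exact discretization of the integrated OU model at
#' irregular times, adding Gaussian measurement error. Used for
#' parameter-recovery checks of [fit_ctcrw()].
#'
#' @param n number of fixes.
#' @param beta_vel,sigma_vel,tau_obs model parameters.
#' @param gap_range range (seconds) of the uniform inter-fix gaps.
#' @param seed optional integer seed.
#' @param start numeric length-2 start position (m).
#' @return data.frame with columns \code{t_s}, \code{x_m}, \code{y_m} and
#'   attribute \code{truth} holding the noise-free positions.
#' @export
simulate_ctcrw <- function(n, beta_vel, sigma_vel, tau_obs,
                           gap_range = c(1.301, 5.862), seed = NULL,
                           start = c(0, 0)) {
  if (!is.null(seed)) set.seed(seed)
  dt <- runif(n - 1, gap_range[1], gap_range[2])
  t <- c(0, cumsum(dt))
  sigma2 <- sigma_vel^2
  pos <- matrix(0, n, 2)
  tru <- matrix(0, n, 2)
  for (ax in 1:2) {
    x <- start[ax]
    v <- rnorm(1, 0, sqrt(sigma2 / (2 * beta_vel)))  # stationary velocity
    tru[1, ax] <- x
    for (i in seq_len(n - 1)) {
      mm <- iou_moments(beta_vel, sigma2, dt[i])
      S <- matrix(c(mm$q11, mm$q12, mm$q12, mm$q22), 2)
      # chol() is upper triangular: t(chol) %*% z has covariance S
      z <- drop(t(chol(S + diag(1e-14, 2))) %*% rnorm(2))
      x_new <- x + mm$phi * v + z[1]
      v <- mm$e * v + z[2]
      x <- x_new
      tru[i + 1, ax] <- x
    }
    pos[, ax] <- tru[, ax] + rnorm(n, 0, tau_obs)
  }
  out <- data.frame(t_s = t, x_m = pos[, 1], y_m = pos[, 2])
  attr(out, "truth") <- data.frame(t_s = t, x_m = tru[, 1], y_m = tru[, 2])
  out
}

# Kalman filter + RTS smoother for one axis over a merged time sequence;
# obs is NA at prediction-only times. Returns smoothed mean and variance of
# the position component.
smooth_axis <- function(times, obs, beta, sigma2, tau2, init_var = 1e4) {
  n <- length(times)
  # filtered and predicted moments
  fm <- matrix(0, n, 2); fP <- array(0, c(n, 2, 2))
  pm <- matrix(0, n, 2); pP <- array(0, c(n, 2, 2))
  first_obs <- which(!is.na(obs))[1]
  m <- c(obs[first_obs], 0)
  P <- matrix(c(init_var, 0, 0, sigma2 / (2 * beta)), 2)
  for (i in seq_len(n)) {
    if (i > 1) {
      dt <- times[i] - times[i - 1]
      mm <- iou_moments(beta, sigma2, dt)
      A <- matrix(c(1, 0, mm$phi, mm$e), 2)
      Q <- matrix(c(mm$q11, mm$q12, mm$q12, mm$q22), 2)
      m <- drop(A %*% m)
      P <- A %*% P %*% t(A) + Q
    }
    pm[i, ] <- m; pP[i, , ] <- P
    if (!is.na(obs[i])) {
      Fv <- P[1, 1] + tau2
      K <- P[, 1] / Fv
      m <- m + K * (obs[i] - m[1])
      P <- P - K %*% t(P[1, ])
    }
    fm[i, ] <- m; fP[i, , ] <- P
  }
  sm <- fm; sP <- fP
  if (n > 1) {
    for (i in (n - 1):1) {
      dt <- times[i + 1] - times[i]
      mm <- iou_moments(beta, sigma2, dt)
      A <- matrix(c(1, 0, mm$phi, mm$e), 2)
      Pp <- pP[i + 1, , ]
      J <- fP[i, , ] %*% t(A) %*% solve(Pp + diag(1e-12, 2))
      sm[i, ] <- fm[i, ] + drop(J %*% (sm[i + 1, ] - pm[i + 1, ]))
      sP[i, , ] <- fP[i, , ] + J %*% (sP[i + 1, , ] - Pp) %*% t(J)
    }
  }
  list(mean = sm[, 1], var = pmax(sP[, 1, 1], 0))
}

#' Predict positions on a regular grid from irregular fixes
#'
#' Runs the CTCRW Kalman smoother over the union of fix times and a regular
#' grid anchored at the first fix, and returns the smoothed positions (and
#' prediction SEs) at the grid times. The grid never extends beyond the last
#' fix.
#'
#' @param fixes data.frame with \code{t_s}, \code{x_m}, \code{y_m} (and
#'   optionally \code{fish_id}, \code{trial_id}, carried through).
#' @param params a \code{ctcrw_fit} or list with \code{beta_vel},
#'   \code{sigma_vel}, \code{tau_obs}.
#' @param dt_s grid spacing in seconds (> 0); default 6.
#' @return data.frame (class \code{regular_track}) with columns
#'   \code{fish_id}, \code{trial_id} (if present in \code{fixes}),
#'   \code{t_s}, \code{x_m}, \code{y_m}, \code{x_se_m}, \code{y_se_m}.
#' @export
predict_regular <- function(fixes, params, dt_s = 6) {
  if (!is_scalar_number(dt_s) || dt_s <= 0)
    abort("`dt_s` must be a positive number of seconds", "carplock_invalid_grid")
  validate_fixes(fixes, min_n = 2L)
  beta <- params$beta_vel; sigma2 <- params$sigma_vel^2
  tau2 <- params$tau_obs^2
  t0 <- fixes$t_s[1]
  grid <- t0 + dt_s * seq(0, floor((fixes$t_s[nrow(fixes)] - t0) / dt_s))
  # merge grid and fix times; a grid time within 1e-9 s of a fix is that fix
  all_t <- sort(unique(c(grid, fixes$t_s)))
  keep <- c(TRUE, diff(all_t) > 1e-9)
  all_t <- all_t[keep]
  obs_idx <- findInterval(fixes$t_s + 1e-12, all_t)
  grid_idx <- findInterval(grid + 1e-12, all_t)
  ox <- rep(NA_real_, length(all_t)); oy <- ox
  ox[obs_idx] <- fixes$x_m; oy[obs_idx] <- fixes$y_m
  sx <- smooth_axis(all_t, ox, beta, sigma2, tau2)
  sy <- smooth_axis(all_t, oy, beta, sigma2, tau2)
  out <- data.frame(
    t_s = grid,
    x_m = sx$mean[grid_idx], y_m = sy$mean[grid_idx],
    x_se_m = sqrt(sx$var[grid_idx]), y_se_m = sqrt(sy$var[grid_idx])
  )
  for (col in c("trial_id", "fish_id"))
    if (!is.null(fixes[[col]])) out[[col]] <- fixes[[col]][1]
  class(out) <- c("regular_track", "data.frame")
  out
}
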