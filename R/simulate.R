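#' Simulate step-angle series directly from the movement HMM
#'
#' Draws latent two-state chains and state-conditional (step, angle)
#' emissions at given per-step covariates, without the spatial arena layer.
#' This is the generator used for parameter-recovery and residual-calibration
#' checks, where the observation model is exactly the HMM.
#'
#' @param params true \code{hmm_params}.
#' @param covariates data.frame with one row per step supplying the design
#'   covariates (e.g. \code{trial_id}, \code{pump_on}, \code{co2_mgL},
#'   \code{temp_C}); recycled for every track.
#' @param n_tracks number of independent fish-tracks.
#' @param design list of design formulas as from [hmm_design()].
#' @param seed optional integer seed.
#' @param fish_prefix prefix for generated fish ids.
#' @return step-angle data.frame with the covariate columns plus
#'   \code{fish_id}, \code{step_index}, \code{step_m}, \code{angle_rad} and
#'   the ground-truth \code{state} column.
#' @export
simulate_step_series <- function(params, covariates, n_tracks = 1,
                                 design = hmm_design(), seed = NULL,
                                 fish_prefix = "sim") {
  if (!is.null(seed)) set.seed(seed)
  cov <- as.data.frame(covariates)
  T <- nrow(cov)
  if (T < 1L) abort("covariates must have at least one row", "carplock_invalid_data")
  Xt <- design_matrix(cov, design$transition)
  Xs <- design_matrix(cov, design$step)
  psi <- transition_probs(params, Xt)
  XsA <- align_design(Xs, rownames(params$step), "step")
  mean_s <- exp(XsA %*% params$step)  # T x 2
  sds <- exp(params$log_sd)
  p0 <- plogis(params$logit_zeromass)

  out <- vector("list", n_tracks)
  for (tr in seq_len(n_tracks)) {
    delta <- if (!is.null(params$delta)) params$delta
             else stationary_delta(psi[1, 1], psi[1, 2])
    st <- integer(T)
    st[1] <- sample.int(2L, 1L, prob = delta)
    if (T > 1) for (t in 2:T) {
      p_switch <- if (st[t - 1] == 1L) psi[t - 1, 1] else psi[t - 1, 2]
      st[t] <- if (runif(1) < p_switch) 3L - st[t - 1] else st[t - 1]
    }
    m <- mean_s[cbind(seq_len(T), st)]
    s <- sds[st]
    step <- rgamma(T, shape = (m / s)^2, scale = s^2 / m)
    zero <- runif(T) < p0[st]
    step[zero] <- 0
    angle <- rep(NA_real_, T)
    for (k in 1:2) {
      sel <- st == k
      if (any(sel))
        angle[sel] <- rvonmises(sum(sel), params$angle_mu[k],
                                params$angle_kappa[k])
    }
    # first angle undefined; zero steps have no bearing
    angle[1] <- NA_real_
    angle[step == 0] <- NA_real_
    angle[c(FALSE, step[-T] == 0)] <- NA_real_
    df <- cov
    df$fish_id <- sprintf("%s%03d", fish_prefix, tr)
    df$step_index <- seq_len(T)
    df$step_m <- step
    df$angle_rad <- angle
    df$state <- st
    out[[tr]] <- df
  }
  do.call(rbind, out)
}

# reflect a coordinate into [0, m] (specular, handles multiple bounces)
reflect_coord <- function(z, m) {
  z <- z %% (2 * m)
  ifelse(z > m, 2 * m - z, z)
}

#' Simulate one experimental trial in the lock arena
#'
#' Simulates \code{n_fish} independent fish: a 6-s latent-state chain driven
#' by the treatment covariates, state-conditional step/turn emissions, and
#' step-turn kinematics (new heading = old heading + turning angle) with
#' specular reflection at the walls. The downstream gate segment is
#' absorbing: a fish whose position crosses \code{gate_x} has exited and its
#' series ends. True positions are then thinned to irregular fix times with
#' uniform inter-fix gaps and isotropic Gaussian position noise, emulating
#' the acoustic positioning system.
#'
#' Fish start uniformly within the upstream two-thirds of the arena with a
#' uniform initial heading; the initial state is drawn from the stationary
#' distribution at the opening covariates.
#'
#' @param arena a [lock_arena()].
#' @param profile a [make_treatment_profile()] profile.
#' @param true_params \code{hmm_params} driving the simulation.
#' @param n_fish number of fish (>= 1).
#' @param seed optional integer seed (identical seed, identical output).
#' @param trial_id identifier stamped on all outputs.
#' @param dt_s latent time step (seconds).
#' @param noise_sd per-axis SD of the Gaussian position noise (m). The
#'   default 1.4826 x 0.878 makes the median per-axis absolute position
#'   error equal the 0.878 m accuracy of the study's positioning system.
#' @param gap_range range (seconds) of uniform inter-fix gaps, matching the
#'   transmitter pulse-rate range 1.301-5.862 s.
#' @param design design formulas mapping covariates to coefficients.
#' @param trial_levels factor levels for the trial covariate when
#'   \code{true_params} carries per-trial effects; defaults to the study
#'   roster's trials.
#' @return object of class \code{sim_trial}: \code{trial_id}, \code{label},
#'   \code{arena}, \code{covariates} (6-s grid), and \code{fish}, a list of
#'   per-fish lists with \code{fixes} (data.frame \code{fish_id},
#'   \code{trial_id}, \code{t_s}, \code{x_m}, \code{y_m}), \code{path} (true
#'   grid positions) and \code{truth} (\code{state_sequence},
#'   \code{exit_time_s}, \code{censored}).
#' @export
simulate_trial <- function(arena, profile, true_params, n_fish, seed = NULL,
                           trial_id = 1L, dt_s = 6,
                           noise_sd = 1.4826 * 0.878,
                           gap_range = c(1.301, 5.862),
                           design = hmm_design(), trial_levels = NULL) {
  stopifnot(inherits(arena, "lock_arena"), inherits(profile, "treatment_profile"))
  if (!is_scalar_number(n_fish) || n_fish < 1)
    abort("`n_fish` must be >= 1", "carplock_invalid_data")
  if (profile$horizon_s <= 0)
    abort("trial horizon must be positive", "carplock_invalid_profile")
  if (!is.null(seed)) set.seed(seed)

  cov <- covariate_series(profile, trial_id, dt_s)
  has_trial_fx <- any(grepl("^trial", rownames(true_params$transition))) ||
    any(grepl("^trial", rownames(true_params$step)))
  if (is.null(trial_levels))
    trial_levels <- if (has_trial_fx) as.character(study_roster()$trial_id)
                    else as.character(trial_id)
  dm_cov <- transform_cov(cov, trial_levels)
  Xt <- stats::model.matrix(design$transition, dm_cov)
  Xs <- stats::model.matrix(design$step, dm_cov)
  psi <- transition_probs(true_params, Xt)
  XsA <- align_design(Xs, rownames(true_params$step), "step")
  mean_s <- exp(XsA %*% true_params$step)
  sds <- exp(true_params$log_sd)
  p0 <- plogis(true_params$logit_zeromass)
  n_steps_max <- nrow(cov) - 1L

  fish <- vector("list", n_fish)
  for (f in seq_len(n_fish)) {
    fid <- sprintf("T%s_F%d", trial_id, f)
    # start in the upstream two-thirds, uniform heading
    pos <- c(runif(1, 0, 2 / 3 * arena$gate_x), runif(1, 0, arena$width))
    heading <- runif(1, -pi, pi)
    delta <- if (!is.null(true_params$delta)) true_params$delta
             else stationary_delta(psi[1, 1], psi[1, 2])
    state <- sample.int(2L, 1L, prob = delta)
    path <- matrix(NA_real_, n_steps_max + 1L, 2)
    path[1, ] <- pos
    states <- integer(0)
    exit_time <- NA_real_
    k_end <- n_steps_max
    for (k in seq_len(n_steps_max)) {
      states <- c(states, state)
      m <- mean_s[k, state]; s <- sds[state]
      if (runif(1) < p0[state]) {
        step <- 0
      } else {
        step <- rgamma(1, shape = (m / s)^2, scale = s^2 / m)
        heading <- heading + rvonmises(1, true_params$angle_mu[state],
                                       true_params$angle_kappa[state])
      }
      new <- pos + step * c(cos(heading), sin(heading))
      if (new[1] >= arena$gate_x && step > 0) {
        # absorbing gate: interpolate the crossing time within the step
        frac <- (arena$gate_x - pos[1]) / (new[1] - pos[1])
        exit_time <- (k - 1) * dt_s + max(frac, 0) * dt_s
        path[k + 1L, ] <- new
        k_end <- k
        break
      }
      # specular reflection at the remaining three walls
      if (new[1] < 0) { new[1] <- -new[1]; heading <- pi - heading }
      if (new[2] < 0 || new[2] > arena$width) {
        new[2] <- reflect_coord(new[2], arena$width)
        heading <- -heading
      }
      heading <- wrap_angle(heading)
      pos <- new
      path[k + 1L, ] <- pos
      # latent chain evolves with the matrix at the step's start covariates
      p_switch <- if (state == 1L) psi[k, 1] else psi[k, 2]
      if (runif(1) < p_switch) state <- 3L - state
    }
    keep <- seq_len(k_end + 1L)
    path <- path[keep, , drop = FALSE]
    grid_t <- (keep - 1L) * dt_s
    t_last <- if (is.na(exit_time)) grid_t[length(grid_t)] else exit_time

    # thin to irregular fix times and add positioning noise
    ft <- 0
    repeat {
      nxt <- ft[length(ft)] + runif(1, gap_range[1], gap_range[2])
      if (nxt > t_last) break
      ft <- c(ft, nxt)
    }
    fx <- approx(grid_t, path[, 1], xout = ft)$y + rnorm(length(ft), 0, noise_sd)
    fy <- approx(grid_t, path[, 2], xout = ft)$y + rnorm(length(ft), 0, noise_sd)
    fish[[f]] <- list(
      fixes = data.frame(fish_id = fid, trial_id = trial_id, t_s = ft,
                         x_m = fx, y_m = fy),
      path = data.frame(fish_id = fid, trial_id = trial_id, t_s = grid_t,
                        x_m = path[, 1], y_m = path[, 2]),
      truth = list(fish_id = fid, state_sequence = states,
                   exit_time_s = exit_time,
                   censored = is.na(exit_time))
    )
  }
  structure(list(trial_id = trial_id, label = profile$label, arena = arena,
                 profile = profile, covariates = cov, fish = fish,
                 true_params = true_params, seed = seed),
            class = "sim_trial")
}

# build the derived-covariate frame used by simulate_trial when per-trial
# effects are present (trial factor with externally fixed levels)
transform_cov <- function(df, trial_levels) {
  df$trial <- factor(as.character(df$trial_id), levels = trial_levels)
  df$pump_off <- 1 - df$pump_on
  df
}

#' @export
print.sim_trial <- function(x, ...) {
  n_exit <- sum(!vapply(x$fish, function(f) f$truth$censored, logical(1)))
  cat(sprintf("Simulated trial %s (%s): %d fish, %d exited before horizon\n",
              x$trial_id, x$label, length(x$fish), n_exit))
  invisible(x)
}

#' Write simulated trials as delimited-text fixtures
#'
#' Per trial: one covariate table, one truth table and one fix table per
#' fish, plus a JSON manifest tying them together. The files round-trip
#' through [read_fixtures()].
#'
#' @param trials list of \code{sim_trial} objects (nonempty).
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
write_fixtures <- function(trials, directory) {
  if (length(trials) == 0L)
    abort("`trials` must be a nonempty list of sim_trial objects",
          "carplock_invalid_data")
  if (inherits(trials, "sim_trial")) trials <- list(trials)
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    abort(sprintf("cannot create directory '%s'", directory), "carplock_io_error")
  manifest <- list(trials = list())
  for (tr in trials) {
    tid <- tr$trial_id
    cov_file <- sprintf("covariates_trial%s.csv", tid)
    write.csv(tr$covariates, file.path(directory, cov_file), row.names = FALSE)
    fix_files <- character(0)
    truth_rows <- list()
    for (f in tr$fish) {
      ff <- sprintf("fixes_trial%s_%s.csv", tid, f$truth$fish_id)
      write.csv(f$fixes, file.path(directory, ff), row.names = FALSE)
      fix_files <- c(fix_files, ff)
      ns <- length(f$truth$state_sequence)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        fish_id = f$truth$fish_id, step_index = seq_len(ns),
        state = f$truth$state_sequence,
        exit_time_s = if (f$truth$censored) NA_real_ else f$truth$exit_time_s,
        censored = f$truth$censored)
    }
    truth_file <- sprintf("truth_trial%s.csv", tid)
    write.csv(do.call(rbind, truth_rows), file.path(directory, truth_file),
              row.names = FALSE)
    manifest$trials[[as.character(tid)]] <- list(
      trial_id = tid, treatment = tr$label,
      covariates = cov_file, truth = truth_file, fixes = as.list(fix_files),
      n_fish = length(tr$fish))
  }
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read fixtures written by [write_fixtures()]
#'
#' @param directory directory holding \code{manifest.json} and the CSVs.
#' @return list with one element per trial: \code{trial_id},
#'   \code{treatment}, \code{covariates}, \code{truth} (data.frames) and
#'   \code{fixes}, a list of per-fish fix data.frames.
#' @export
read_fixtures <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf))
    abort(sprintf("no manifest.json under '%s'", directory), "carplock_io_error")
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  lapply(manifest$trials, function(tr) {
    list(trial_id = tr$trial_id, treatment = tr$treatment,
         covariates = read.csv(file.path(directory, tr$covariates)),
         truth = read.csv(file.path(directory, tr$truth)),
         fixes = lapply(tr$fixes, function(f) read.csv(file.path(directory, f))))
  })
}
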