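#' Validate and complete a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or takes an equivalent list), checks
#' it against the schema, fills defaults (6-s grid, 90-min horizon, study
#' arena and roster) and materializes the seed. Validation failures name the
#' offending keys before any computation starts.
#'
#' @param config path to a \code{.yaml}/\code{.yml}/\code{.json} file, or a
#'   list with the same structure.
#' @return object of class \code{pipeline_config}.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort(sprintf("config file '%s' does not exist", config), "carplock_io_error")
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config))
    abort("config must be a list or a YAML/JSON file path", "carplock_config_error")

  known <- c("seed", "output_dir", "dt_s", "horizon_min", "arena",
             "simulate", "hmm")
  bad <- setdiff(names(config), known)
  offending <- character(0)
  if (length(bad)) offending <- c(offending, bad)

  cfg <- list(
    seed = config$seed %||% NA,
    output_dir = config$output_dir %||% tempfile("carplock_run_"),
    dt_s = config$dt_s %||% 6,
    horizon_min = config$horizon_min %||% 90,
    arena = config$arena %||% list(),
    simulate = config$simulate %||% list(),
    hmm = config$hmm %||% list()
  )
  if (is.na(cfg$seed[1])) cfg$seed <- sample.int(1e6, 1)  # recorded in report
  if (!is_scalar_number(cfg$seed)) offending <- c(offending, "seed")
  if (!is_scalar_number(cfg$dt_s) || cfg$dt_s <= 0) offending <- c(offending, "dt_s")
  if (!is_scalar_number(cfg$horizon_min) || cfg$horizon_min <= 0)
    offending <- c(offending, "horizon_min")

  ar <- cfg$arena
  cfg$arena <- tryCatch(
    lock_arena(length = ar$length %||% 51.82, width = ar$width %||% 11.12,
               gate_x = ar$gate_x %||% ar$length %||% 51.82),
    carplock_error = function(e) { offending <<- c(offending, "arena"); NULL })

  sim_known <- c("roster", "ramp_minutes", "target_co2", "noise_sd",
                 "gap_range", "trial_effects")
  offending <- c(offending, paste0("simulate.", recycle0 = TRUE,
                                   setdiff(names(cfg$simulate), sim_known)))
  sm <- cfg$simulate
  roster <- sm$roster %||% study_roster()
  if (!is.data.frame(roster)) roster <- do.call(rbind, lapply(roster, as.data.frame))
  if (!all(c("trial_id", "treatment", "n_fish") %in% names(roster)) ||
      nrow(roster) == 0 || !all(roster$treatment %in% TREATMENT_LABELS) ||
      anyNA(roster$trial_id) || any(roster$n_fish < 1) ||
      anyDuplicated(roster$trial_id))
    offending <- c(offending, "simulate.roster")
  if (is.null(roster$temp_C)) roster$temp_C <- 22
  cfg$simulate <- list(
    roster = roster,
    ramp_minutes = sm$ramp_minutes %||% 7.5,
    target_co2 = sm$target_co2 %||% 125,
    noise_sd = sm$noise_sd %||% (1.4826 * 0.878),
    gap_range = sm$gap_range %||% c(1.301, 5.862),
    trial_effects = isTRUE(sm$trial_effects %||% FALSE)
  )
  if (!is_scalar_number(cfg$simulate$target_co2) || cfg$simulate$target_co2 < 0)
    offending <- c(offending, "simulate.target_co2")
  if (!is_scalar_number(cfg$simulate$ramp_minutes) || cfg$simulate$ramp_minutes <= 0)
    offending <- c(offending, "simulate.ramp_minutes")
  if (!is_scalar_number(cfg$simulate$noise_sd) || cfg$simulate$noise_sd < 0)
    offending <- c(offending, "simulate.noise_sd")

  hmm_known <- c("trial", "pump", "co2", "temp", "n_restarts", "compute_se")
  offending <- c(offending, paste0("hmm.", setdiff(names(cfg$hmm), hmm_known), recycle0 = TRUE))
  hm <- cfg$hmm
  cfg$hmm <- list(
    trial = isTRUE(hm$trial %||% FALSE),
    pump = isTRUE(hm$pump %||% TRUE),
    co2 = isTRUE(hm$co2 %||% TRUE),
    temp = isTRUE(hm$temp %||% TRUE),
    n_restarts = hm$n_restarts %||% 2,
    compute_se = isTRUE(hm$compute_se %||% FALSE)
  )

  if (length(offending))
    abort(paste0("invalid configuration keys: ",
                 paste(unique(offending), collapse = ", ")),
          "carplock_config_error", keys = unique(offending))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          "carplock_stage_error", stage = name)
  })
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

# exit record for the pipeline: gate crossing on the smoothed track, else
# end of detections well before the horizon (transmitter left the lock),
# else censored at the horizon
pipeline_exit_record <- function(track, arena, horizon_min, treatment) {
  rec <- detect_exit(track, arena, horizon_min, treatment)
  last_min <- (track$t_s[nrow(track)] - track$t_s[1]) / 60
  if (rec$event == 0L && last_min < horizon_min - 1) {
    rec$time_min <- max(last_min, 1e-3)
    rec$event <- 1L
  }
  rec
}

#' Run the full simulate-regularize-fit-decode-summarize pipeline
#'
#' Executes every stage on a synthetic experiment defined by the
#' configuration, persisting each intermediate table under
#' \code{output_dir}: simulated fixtures, regularized tracks, step-angle
#' series, the fitted coefficient table, decoded states, pseudo-residuals,
#' exit records, per-treatment Kaplan-Meier curves and a JSON run report.
#' All randomness derives from the configured seed, so a fixed configuration
#' reproduces the report byte-identically.
#'
#' @param config a \code{pipeline_config} from [validate_config()], or a
#'   path/list accepted by it.
#' @return the run report, invisibly (also written to
#'   \code{output_dir/report.json}).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(seed = cfg$seed, dt_s = cfg$dt_s, horizon_min = cfg$horizon_min,
         arena = unclass(cfg$arena), simulate = cfg$simulate, hmm = cfg$hmm),
    file.path(out, "config.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  config_hash <- unname(tools::md5sum(file.path(out, "config.json")))

  roster <- cfg$simulate$roster
  params <- default_hmm_params(trial_effects = cfg$simulate$trial_effects)
  sim_design <- hmm_design(trial = cfg$simulate$trial_effects)
  trial_levels <- as.character(roster$trial_id)

  trials <- stage("simulate", {
    lapply(seq_len(nrow(roster)), function(i) {
      pr <- make_treatment_profile(
        roster$treatment[i], horizon_s = cfg$horizon_min * 60,
        ramp_minutes = cfg$simulate$ramp_minutes,
        target_co2 = cfg$simulate$target_co2,
        temperature = roster$temp_C[i])
      simulate_trial(cfg$arena, pr, params, n_fish = roster$n_fish[i],
                     seed = cfg$seed + 1000L + i,
                     trial_id = roster$trial_id[i], dt_s = cfg$dt_s,
                     noise_sd = cfg$simulate$noise_sd,
                     gap_range = cfg$simulate$gap_range,
                     design = sim_design, trial_levels = trial_levels)
    })
  })
  stage("fixtures", write_fixtures(trials, file.path(out, "sim")))

  reg <- stage("regularize", {
    tracks <- list(); dropped <- character(0)
    for (tr in trials) for (f in tr$fish) {
      if (nrow(f$fixes) < 10) { dropped <- c(dropped, f$fixes$fish_id[1]); next }
      fit <- fit_ctcrw(f$fixes)
      tracks[[length(tracks) + 1L]] <- predict_regular(f$fixes, fit, cfg$dt_s)
    }
    if (length(dropped))
      message(sprintf("  dropped %d fish with < 10 fixes: %s", length(dropped),
                      paste(dropped, collapse = ", ")))
    list(tracks = tracks, dropped = dropped)
  })
  tracks_df <- do.call(rbind, lapply(reg$tracks, as.data.frame))
  write.csv(tracks_df, file.path(out, "tracks.csv"), row.names = FALSE)

  cov_by_trial <- setNames(
    lapply(trials, `[[`, "covariates"),
    vapply(trials, function(t) as.character(t$trial_id), character(1)))
  label_by_trial <- setNames(vapply(trials, `[[`, NA_character_, "label"),
                             names(cov_by_trial))

  steps <- stage("features", {
    parts <- lapply(reg$tracks, function(trk) {
      if (nrow(trk) < 3) return(NULL)
      steps_and_angles(trk, cov_by_trial[[as.character(trk$trial_id[1])]])
    })
    do.call(rbind, Filter(Negate(is.null), parts))
  })
  write.csv(steps, file.path(out, "steps.csv"), row.names = FALSE)

  design <- hmm_design(trial = cfg$hmm$trial, pump = cfg$hmm$pump,
                       co2 = cfg$hmm$co2, temp = cfg$hmm$temp)
  fit <- stage("fit", {
    fit_hmm(steps, design, n_restarts = cfg$hmm$n_restarts, seed = cfg$seed,
            compute_se = cfg$hmm$compute_se)
  })
  coef_tab <- coefficient_table(fit)
  write.csv(coef_tab, file.path(out, "coefficients.csv"), row.names = FALSE)

  dec <- stage("decode", {
    vit <- viterbi(fit$params_hat, steps, design)
    post <- state_probabilities(fit$params_hat, steps, design)
    res <- pseudo_residuals(fit$params_hat, steps, design)
    list(vit = vit, post = post, res = res)
  })
  decoded <- dec$vit
  decoded$p_state1 <- dec$post$p_state1
  write.csv(decoded, file.path(out, "decoded.csv"), row.names = FALSE)
  write.csv(dec$res, file.path(out, "residuals.csv"), row.names = FALSE)

  surv <- stage("survival", {
    recs <- do.call(rbind, lapply(reg$tracks, function(trk) {
      pipeline_exit_record(trk, cfg$arena, cfg$horizon_min,
                           label_by_trial[[as.character(trk$trial_id[1])]])
    }))
    write.csv(recs, file.path(out, "exits.csv"), row.names = FALSE)
    by_tr <- split(recs, recs$treatment)
    km <- lapply(names(by_tr), function(lab) {
      r <- by_tr[[lab]]
      k <- km_estimate(r)
      write.csv(
        data.frame(time_min = k$time, n_risk = k$n_risk, n_event = k$n_event,
                   survival = k$survival, greenwood_se = k$greenwood_se),
        file.path(out, sprintf("km_%s.csv", lab)), row.names = FALSE)
      rem <- remaining_proportion(sum(r$event == 0), nrow(r))
      med <- median_exit(r, cfg$horizon_min)
      list(treatment = lab, n = nrow(r), n_exited = sum(r$event == 1),
           median_exit_min = med$median_min, km_median_min = med$km_median_min,
           p_remaining_percent = rem$p_percent,
           se_remaining_percent = rem$se_percent)
    })
    list(records = recs, km = setNames(km, names(by_tr)))
  })

  budget <- stage("budgets", {
    b <- state_time_budget(dec$vit, surv$records, cfg$horizon_min)
    write.csv(b$per_fish, file.path(out, "budgets.csv"), row.names = FALSE)
    b
  })

  report <- stage("report", {
    rp <- list(
      provenance = list(
        package = "carplock",
        version = as.character(utils::packageVersion("carplock")),
        seed = cfg$seed, config_hash = config_hash),
      counts = list(n_trials = length(trials),
                    n_fish = sum(roster$n_fish),
                    n_fish_analyzed = length(reg$tracks),
                    n_fish_dropped = length(reg$dropped),
                    n_steps = nrow(steps)),
      km = surv$km,
      coefficients = coef_tab,
      state_budget = list(
        overall_fraction_exploratory = budget$overall_fraction,
        n_state1 = budget$n_state1, n_total = budget$n_total,
        per_fish = budget$per_fish),
      residual_diagnostics = list(
        step_mean = mean(dec$res$step_resid[is.finite(dec$res$step_resid)]),
        step_sd = sd(dec$res$step_resid[is.finite(dec$res$step_resid)]),
        angle_mean = mean(dec$res$angle_resid[is.finite(dec$res$angle_resid)]),
        angle_sd = sd(dec$res$angle_resid[is.finite(dec$res$angle_resid)])),
      hmm = list(loglik = fit$loglik, converged = fit$convergence,
                 n_restarts_used = fit$n_restarts_used)
    )
    jsonlite::write_json(rp, file.path(out, "report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = 10)
    rp
  })
  invisible(report)
}
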