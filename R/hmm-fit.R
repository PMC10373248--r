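# Internal: validate a step-angle table, order it track-contiguously and
# precompute everything the likelihood needs.
prepare_hmm_data <- function(data, design) {
  data <- as.data.frame(data)
  req <- c("fish_id", "step_m")
  if (!all(req %in% names(data)))
    abort("data must have columns fish_id and step_m", "carplock_invalid_data")
  if (nrow(data) == 0L)
    abort("data is empty", "carplock_invalid_data")
  if (is.null(data$angle_rad)) data$angle_rad <- NA_real_
  if (any(data$step_m < 0, na.rm = TRUE))
    abort("step lengths must be nonnegative", "carplock_invalid_data")

  ids <- unique(data$fish_id)
  ord <- order(match(data$fish_id, ids))
  data <- data[ord, , drop = FALSE]

  vars <- union(all.vars(design$transition), all.vars(design$step))
  vars <- intersect(union(vars, c("trial_id", "pump_on")), names(data))
  bad <- if (length(vars)) which(rowSums(is.na(data[, vars, drop = FALSE])) > 0)
         else integer(0)
  if (length(bad)) {
    b <- bad[1]
    abort(sprintf("missing covariate values (first at fish %s, step %s)",
                  data$fish_id[b], data$step_index[b] %||% b),
          "carplock_invalid_data")
  }

  Xt <- design_matrix(data, design$transition)
  Xs <- design_matrix(data, design$step)
  len <- as.integer(table(factor(data$fish_id, levels = ids)))
  start <- c(1L, cumsum(len)[-length(len)] + 1L)
  list(data = data, Xt = Xt, Xs = Xs, ids = ids,
       track_start = as.integer(start), track_len = len,
       step = data$step_m, angle = data$angle_rad)
}

# T x 2 combined log emission density (step x angle) given aligned designs
emission_logdens <- function(params, prep) {
  cbind(
    step_density(prep$step, 1L, params, prep$Xs, log = TRUE) +
      angle_density(prep$angle, 1L, params, log = TRUE),
    step_density(prep$step, 2L, params, prep$Xs, log = TRUE) +
      angle_density(prep$angle, 2L, params, log = TRUE)
  )
}

# n_tracks x 2 initial distributions: free delta if given, else stationary
# at each track's first-step covariates
initial_deltas <- function(params, psi, track_start) {
  if (!is.null(params$delta))
    return(matrix(params$delta, length(track_start), 2, byrow = TRUE))
  t(vapply(track_start,
           function(s) stationary_delta(psi[s, 1], psi[s, 2]),
           numeric(2)))
}

#' Forward-algorithm log-likelihood of the two-state movement HMM
#'
#' Sums the log-likelihood over independent fish-tracks using the scaled
#' forward recursion, with a per-step transition matrix (evaluated at the
#' covariates of the step being left) and zero-inflated-gamma x von Mises
#' emissions. Missing angles contribute a factor of one.
#'
#' @param params an \code{hmm_params} object.
#' @param data step-angle table (one or more fish, identified by
#'   \code{fish_id}) as produced by [steps_and_angles()] or
#'   [simulate_step_series()].
#' @param design list of formulas as from [hmm_design()].
#' @return scalar log-likelihood.
#' @export
loglik_forward <- function(params, data, design = hmm_design()) {
  prep <- prepare_hmm_data(data, design)
  psi <- transition_probs(params, prep$Xt)
  logemis <- emission_logdens(params, prep)
  delta <- initial_deltas(params, psi, prep$track_start)
  forward_loglik_cpp(logemis, psi, delta, prep$track_start, prep$track_len)
}

# ---- working-scale packing ---------------------------------------------

make_layout <- function(pt_names, ps_names, est_zeromass, est_delta) {
  nm <- c(
    paste0("trans.1to2.", pt_names), paste0("trans.2to1.", pt_names),
    paste0("step.state1.", ps_names), paste0("step.state2.", ps_names),
    "log_sd.state1", "log_sd.state2",
    if (est_zeromass) c("zeromass.state1", "zeromass.state2"),
    "angle_mu.state1", "angle_mu.state2",
    "log_kappa.state1", "log_kappa.state2",
    if (est_delta) "delta.logit1"
  )
  list(names = nm, pt = length(pt_names), ps = length(ps_names),
       pt_names = pt_names, ps_names = ps_names,
       est_zeromass = est_zeromass, est_delta = est_delta,
       npar = length(nm))
}

unpack_params <- function(w, layout) {
  pt <- layout$pt; ps <- layout$ps
  i <- 0L
  tr <- matrix(w[i + seq_len(2 * pt)], pt, 2); i <- i + 2 * pt
  st <- matrix(w[i + seq_len(2 * ps)], ps, 2); i <- i + 2 * ps
  rownames(tr) <- layout$pt_names; rownames(st) <- layout$ps_names
  log_sd <- w[i + 1:2]; i <- i + 2L
  if (layout$est_zeromass) { lzm <- w[i + 1:2]; i <- i + 2L }
  else lzm <- c(-Inf, -Inf)
  mu <- wrap_angle(w[i + 1:2]); i <- i + 2L
  kappa <- exp(w[i + 1:2]); i <- i + 2L
  delta <- if (layout$est_delta) {
    d1 <- plogis(w[i + 1L]); c(d1, 1 - d1)
  } else NULL
  hmm_params(transition = tr, step = st, log_sd = log_sd,
             logit_zeromass = lzm, angle_mu = mu, angle_kappa = kappa,
             delta = delta)
}

start_values <- function(prep, layout) {
  s <- prep$step[!is.na(prep$step) & prep$step > 0]
  med <- median(s)
  hi <- s[s > med]; lo <- s[s <= med]
  m1 <- log(mean(hi)); m2 <- log(max(mean(lo), 1e-6))
  sd1 <- log(max(sd(hi), mean(hi) * 0.5, 1e-6))
  sd2 <- log(max(sd(lo), mean(lo) * 0.5, 1e-6))
  w <- numeric(layout$npar)
  names(w) <- layout$names
  w[paste0("trans.1to2.", layout$pt_names[1])] <- qlogis(0.1)
  w[paste0("trans.2to1.", layout$pt_names[1])] <- qlogis(0.1)
  w[paste0("step.state1.", layout$ps_names[1])] <- m1
  w[paste0("step.state2.", layout$ps_names[1])] <- m2
  w["log_sd.state1"] <- sd1; w["log_sd.state2"] <- sd2
  if (layout$est_zeromass) {
    pz <- max(mean(prep$step == 0, na.rm = TRUE), 1e-4)
    w[c("zeromass.state1", "zeromass.state2")] <- qlogis(pz)
  }
  w[c("log_kappa.state1", "log_kappa.state2")] <- log(0.5)
  if (layout$est_delta) w["delta.logit1"] <- 0
  w
}

swap_names <- function(nm) {
  nm <- gsub("1to2", "@@dir@@", nm, fixed = TRUE)
  nm <- gsub("2to1", "1to2", nm, fixed = TRUE)
  nm <- gsub("@@dir@@", "2to1", nm, fixed = TRUE)
  nm <- gsub("state1", "@@st@@", nm, fixed = TRUE)
  nm <- gsub("state2", "state1", nm, fixed = TRUE)
  gsub("@@st@@", "state2", nm, fixed = TRUE)
}

#' Fit the two-state movement HMM by maximum likelihood
#'
#' Maximizes the forward-algorithm likelihood over all working-scale
#' parameters (logit transition coefficients, log-mean step coefficients,
#' log step SD, logit zero mass, von Mises mean and log concentration) by
#' quasi-Newton optimization with seeded random restarts. After fitting,
#' states are ordered so state 1 ("exploratory") has the larger baseline
#' mean step length. Standard errors come from the inverse observed
#' information (numerically differentiated Hessian).
#'
#' The zero-mass parameters are estimated only when the data contain exact
#' zero steps (\code{zeromass = "auto"}); otherwise the point mass is fixed
#' at zero probability.
#'
#' @param data step-angle table; two or more fish-tracks recommended.
#' @param design list of formulas as from [hmm_design()], selecting which
#'   covariates enter the transition and step-mean linear predictors.
#' @param n_restarts number of optimization starts (first is a data-driven
#'   heuristic, the rest are seeded random perturbations of it).
#' @param seed integer seed for the restart perturbations.
#' @param compute_se logical: compute Wald standard errors (adds one Hessian
#'   evaluation).
#' @param zeromass \code{"auto"} or \code{"none"}.
#' @param estimate_delta logical: estimate a free (shared) initial state
#'   distribution instead of the per-track stationary default.
#' @param maxit,reltol optimizer control.
#' @return object of class \code{hmm_fit}: \code{params_hat}
#'   (\code{hmm_params}), \code{loglik}, \code{n_obs}, \code{n_tracks},
#'   \code{convergence}, \code{se} (named, working scale), \code{vcov},
#'   \code{n_restarts_used}, \code{design}.
#' @export
fit_hmm <- function(data, design = hmm_design(), n_restarts = 5, seed = 1,
                    compute_se = TRUE, zeromass = c("auto", "none"),
                    estimate_delta = FALSE, maxit = 1000, reltol = 1e-9) {
  zeromass <- match.arg(zeromass)
  prep <- prepare_hmm_data(data, design)
  if (length(prep$ids) < 2L)
    message("fit_hmm: a single track was supplied; two or more are recommended")
  est_zm <- zeromass == "auto" && any(prep$step == 0, na.rm = TRUE)
  layout <- make_layout(colnames(prep$Xt), colnames(prep$Xs), est_zm,
                        estimate_delta)

  negll <- function(w) {
    params <- tryCatch(unpack_params(w, layout), error = function(e) NULL)
    if (is.null(params)) return(1e12)
    psi <- transition_probs(params, prep$Xt)
    # extreme working values can overflow dgamma; the guard below catches them
    logemis <- suppressWarnings(emission_logdens(params, prep))
    logemis[is.nan(logemis)] <- -Inf
    delta <- initial_deltas(params, psi, prep$track_start)
    ll <- forward_loglik_cpp(logemis, psi, delta, prep$track_start,
                             prep$track_len)
    if (!is.finite(ll)) 1e12 else -ll
  }

  w0 <- start_values(prep, layout)
  best <- NULL; used <- 0L
  for (r in seq_len(n_restarts)) {
    w <- w0
    if (r > 1L) {
      set.seed(as.integer((seed + r) %% .Machine$integer.max))
      w <- w0 + rnorm(layout$npar, 0, 0.4)
    }
    opt <- tryCatch(
      optim(w, negll, method = "BFGS",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    used <- used + 1L
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e11) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    abort("all HMM optimization restarts failed; check data scaling and design",
          "carplock_hmm_nonconvergence")

  se <- vcov <- NULL
  if (compute_se) {
    H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
    if (!is.null(H)) {
      vcov <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov)) {
        se <- sqrt(pmax(diag(vcov), 0))
        names(se) <- layout$names
        dimnames(vcov) <- list(layout$names, layout$names)
      }
    }
  }

  params <- unpack_params(best$par, layout)
  os <- order_states(params)
  params <- os$params
  if (os$swapped && !is.null(se)) {
    names(se) <- swap_names(names(se))
    se <- se[layout$names]
    dimnames(vcov) <- list(swap_names(rownames(vcov)), swap_names(colnames(vcov)))
    vcov <- vcov[layout$names, layout$names]
  }

  structure(list(
    params_hat = params,
    loglik = -best$value,
    n_obs = nrow(prep$data),
    n_tracks = length(prep$ids),
    convergence = best$convergence == 0,
    se = se, vcov = vcov,
    n_restarts_used = used,
    swapped = os$swapped,
    design = design,
    layout_names = layout$names
  ), class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("Two-state movement HMM fit: %d steps in %d tracks, loglik %.2f%s\n",
              x$n_obs, x$n_tracks, x$loglik,
              if (x$convergence) "" else " (NOT converged)"))
  print(x$params_hat)
  invisible(x)
}

#' Coefficient table of a fitted movement HMM
#'
#' Lays the fitted coefficients out as in the study's reporting convention:
#' one row per parameter, four columns (transition 1->2 and 2->1 logit
#' coefficients; state 1 and state 2 log-mean step coefficients), with the
#' per-state log SD and logit zero mass appended as extra rows.
#'
#' @param fit an \code{hmm_fit}.
#' @return data.frame.
#' @export
coefficient_table <- function(fit) {
  p <- fit$params_hat
  rn <- union(rownames(p$transition), rownames(p$step))
  tab <- data.frame(parameter = c(rn, "Std. deviation", "Zero mass"),
                    trans_1to2 = NA_real_, trans_2to1 = NA_real_,
                    step_state1 = NA_real_, step_state2 = NA_real_)
  it <- match(rownames(p$transition), tab$parameter)
  tab$trans_1to2[it] <- p$transition[, 1]
  tab$trans_2to1[it] <- p$transition[, 2]
  is <- match(rownames(p$step), tab$parameter)
  tab$step_state1[is] <- p$step[, 1]
  tab$step_state2[is] <- p$step[, 2]
  nsd <- tab$parameter == "Std. deviation"
  tab$step_state1[nsd] <- p$log_sd[1]; tab$step_state2[nsd] <- p$log_sd[2]
  nzm <- tab$parameter == "Zero mass"
  tab$step_state1[nzm] <- p$logit_zeromass[1]
  tab$step_state2[nzm] <- p$logit_zeromass[2]
  tab
}
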