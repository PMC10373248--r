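# shared per-call precomputation for the decoding functions
decode_prep <- function(params, data, design) {
  prep <- prepare_hmm_data(data, design)
  if (nrow(prep$data) == 0L)
    abort("empty step series", "carplock_invalid_data")
  prep$psi <- transition_probs(params, prep$Xt)
  prep$logemis <- emission_logdens(params, prep)
  prep$delta <- initial_deltas(params, prep$psi, prep$track_start)
  prep
}

track_indices <- function(prep, tr) {
  prep$track_start[tr] + seq_len(prep$track_len[tr]) - 1L
}

#' Viterbi decoding of behavioral states
#'
#' Jointly most probable state sequence per fish under the fitted (or true)
#' parameters, with per-step transition matrices. Ties are broken toward
#' state 1 (exploratory).
#'
#' @param params an \code{hmm_params} object.
#' @param data step-angle table.
#' @param design list of design formulas as from [hmm_design()].
#' @return data.frame with columns \code{fish_id}, \code{step_index},
#'   \code{state}.
#' @export
viterbi <- function(params, data, design = hmm_design()) {
  prep <- decode_prep(params, data, design)
  out_state <- integer(nrow(prep$data))
  for (tr in seq_along(prep$track_start)) {
    idx <- track_indices(prep, tr)
    T <- length(idx)
    v <- matrix(-Inf, T, 2)
    bp <- matrix(1L, T, 2)
    v[1, ] <- log(prep$delta[tr, ]) + prep$logemis[idx[1], ]
    if (T > 1) for (t in 2:T) {
      p12 <- prep$psi[idx[t - 1], 1]; p21 <- prep$psi[idx[t - 1], 2]
      lG <- log(rbind(c(1 - p12, p12), c(p21, 1 - p21)))
      for (j in 1:2) {
        cand <- v[t - 1, ] + lG[, j]
        bp[t, j] <- which.max(cand)  # which.max prefers state 1 on ties
        v[t, j] <- cand[bp[t, j]] + prep$logemis[idx[t], j]
      }
    }
    s <- integer(T)
    s[T] <- which.max(v[T, ])
    if (T > 1) for (t in (T - 1):1) s[t] <- bp[t + 1, s[t + 1]]
    out_state[idx] <- s
  }
  data.frame(fish_id = prep$data$fish_id,
             step_index = prep$data$step_index %||% unlist(lapply(prep$track_len, seq_len)),
             state = out_state)
}

#' Posterior state probabilities (forward-backward smoothing)
#'
#' @inheritParams viterbi
#' @return data.frame with columns \code{fish_id}, \code{step_index},
#'   \code{p_state1} (posterior probability of the exploratory state;
#'   \code{p_state2 = 1 - p_state1}).
#' @export
state_probabilities <- function(params, data, design = hmm_design()) {
  prep <- decode_prep(params, data, design)
  post <- numeric(nrow(prep$data))
  for (tr in seq_along(prep$track_start)) {
    idx <- track_indices(prep, tr)
    T <- length(idx)
    la <- matrix(0, T, 2)  # scaled forward
    lc <- numeric(T)
    a <- prep$delta[tr, ] * exp(prep$logemis[idx[1], ] -
                                  max(prep$logemis[idx[1], ]))
    la[1, ] <- a / sum(a)
    if (T > 1) for (t in 2:T) {
      p12 <- prep$psi[idx[t - 1], 1]; p21 <- prep$psi[idx[t - 1], 2]
      b <- c(la[t - 1, 1] * (1 - p12) + la[t - 1, 2] * p21,
             la[t - 1, 1] * p12 + la[t - 1, 2] * (1 - p21))
      b <- b * exp(prep$logemis[idx[t], ] - max(prep$logemis[idx[t], ]))
      la[t, ] <- b / sum(b)
    }
    bb <- matrix(1, T, 2)  # scaled backward
    if (T > 1) for (t in (T - 1):1) {
      p12 <- prep$psi[idx[t], 1]; p21 <- prep$psi[idx[t], 2]
      G <- rbind(c(1 - p12, p12), c(p21, 1 - p21))
      e <- exp(prep$logemis[idx[t + 1], ] - max(prep$logemis[idx[t + 1], ]))
      b <- drop(G %*% (e * bb[t + 1, ]))
      bb[t, ] <- b / sum(b)
    }
    p <- la * bb
    post[idx] <- p[, 1] / rowSums(p)
  }
  data.frame(fish_id = prep$data$fish_id,
             step_index = prep$data$step_index %||% unlist(lapply(prep$track_len, seq_len)),
             p_state1 = post)
}

#' Per-fish exploratory time budget against exit time
#'
#' Fraction of decoded steps spent in the exploratory state, per fish and
#' pooled, joined with exit times; censored fish are assigned the trial
#' horizon.
#'
#' @param decoding data.frame from [viterbi()] (or posterior states
#'   thresholded at 0.5), columns \code{fish_id}, \code{state}.
#' @param exit_times data.frame with columns \code{fish_id}, \code{time_min},
#'   \code{event} (1 = exited, 0 = censored).
#' @param horizon_min exit time assigned to censored fish (minutes).
#' @return list with \code{per_fish} (data.frame \code{fish_id},
#'   \code{n_steps}, \code{fraction_exploratory}, \code{exit_min}),
#'   \code{overall_fraction} (pooled step counts) and the pooled counts
#'   \code{n_state1}, \code{n_total}.
#' @export
state_time_budget <- function(decoding, exit_times, horizon_min = 90) {
  if (!all(c("fish_id", "state") %in% names(decoding)))
    abort("decoding needs columns fish_id, state", "carplock_invalid_data")
  if (!all(c("fish_id", "time_min", "event") %in% names(exit_times)))
    abort("exit_times needs columns fish_id, time_min, event",
          "carplock_invalid_data")
  ids <- unique(decoding$fish_id)
  n_steps <- as.integer(table(factor(decoding$fish_id, levels = ids)))
  if (any(n_steps == 0L))
    abort("fish with no decoded steps", "carplock_invalid_data")
  miss <- setdiff(ids, exit_times$fish_id)
  if (length(miss))
    abort(paste0("missing exit record for fish: ", paste(miss, collapse = ", ")),
          "carplock_missing_exit")
  n1 <- vapply(ids, function(id)
    sum(decoding$state[decoding$fish_id == id] == 1L), integer(1))
  m <- match(ids, exit_times$fish_id)
  exit_min <- ifelse(exit_times$event[m] == 1, exit_times$time_min[m],
                     horizon_min)
  per_fish <- data.frame(fish_id = ids, n_steps = n_steps,
                         fraction_exploratory = n1 / n_steps,
                         exit_min = exit_min)
  list(per_fish = per_fish,
       overall_fraction = sum(n1) / sum(n_steps),
       n_state1 = sum(n1), n_total = sum(n_steps))
}

# zero-inflated gamma mixture CDF for one state at given per-step means
zigamma_cdf <- function(step, mean, sd, p0) {
  shape <- (mean / sd)^2
  scale <- sd^2 / mean
  out <- p0 + (1 - p0) * pgamma(step, shape = shape, scale = scale)
  out[!is.na(step) & step == 0] <- p0
  out
}

#' One-step-ahead pseudo-residuals
#'
#' Forecast pseudo-residuals z_t = qnorm(F(y_t | y_1..t-1)) where F mixes the
#' state-conditional CDFs by the forward-predictive state weights. Under a
#' correctly specified model both residual streams are approximately standard
#' normal. The angle CDF is measured from -pi; residuals for missing angles
#' are missing.
#'
#' @inheritParams viterbi
#' @return data.frame with columns \code{fish_id}, \code{step_index},
#'   \code{step_resid}, \code{angle_resid}.
#' @export
pseudo_residuals <- function(params, data, design = hmm_design()) {
  prep <- decode_prep(params, data, design)
  Xs <- align_design(prep$Xs, rownames(params$step), "step")
  mean1 <- exp(drop(Xs %*% params$step[, 1]))
  mean2 <- exp(drop(Xs %*% params$step[, 2]))
  sds <- exp(params$log_sd)
  p0 <- plogis(params$logit_zeromass)
  n <- nrow(prep$data)
  step_res <- numeric(n); angle_res <- rep(NA_real_, n)
  ang_ok <- !is.na(prep$angle)
  # per-state angle CDF values, vectorized once
  Fang1 <- Fang2 <- rep(NA_real_, n)
  if (any(ang_ok)) {
    Fang1[ang_ok] <- pvonmises(prep$angle[ang_ok], params$angle_mu[1],
                               params$angle_kappa[1])
    Fang2[ang_ok] <- pvonmises(prep$angle[ang_ok], params$angle_mu[2],
                               params$angle_kappa[2])
  }
  Fstep1 <- zigamma_cdf(prep$step, mean1, sds[1], p0[1])
  Fstep2 <- zigamma_cdf(prep$step, mean2, sds[2], p0[2])

  for (tr in seq_along(prep$track_start)) {
    idx <- track_indices(prep, tr)
    T <- length(idx)
    w <- prep$delta[tr, ]  # one-step-ahead state weights
    a <- w
    for (t in seq_len(T)) {
      i <- idx[t]
      if (t > 1) {
        p12 <- prep$psi[idx[t - 1], 1]; p21 <- prep$psi[idx[t - 1], 2]
        w <- c(a[1] * (1 - p12) + a[2] * p21,
               a[1] * p12 + a[2] * (1 - p21))
      }
      step_res[i] <- qnorm(w[1] * Fstep1[i] + w[2] * Fstep2[i])
      if (ang_ok[i])
        angle_res[i] <- qnorm(w[1] * Fang1[i] + w[2] * Fang2[i])
      a <- w * exp(prep$logemis[i, ] - max(prep$logemis[i, ]))
      a <- a / sum(a)
    }
  }
  data.frame(fish_id = prep$data$fish_id,
             step_index = prep$data$step_index %||% unlist(lapply(prep$track_len, seq_len)),
             step_resid = step_res, angle_resid = angle_res)
}
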