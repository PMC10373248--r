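# Independent brute-force oracles and small parameter builders used across
# the suite. The oracles deliberately avoid the package's recursions: they
# enumerate all 2^T state paths with hand-written densities.

# simple two-state parameter set with constant (intercept-only) design
simple_params <- function(psi12 = 0.1, psi21 = 0.15,
                          mean1 = 0.988, mean2 = 0.026,
                          sd1 = 0.928, sd2 = 0.019,
                          zeromass = c(-Inf, -Inf),
                          mu = c(0, 0), kappa = c(0.5, 2), delta = NULL) {
  hmm_params(
    transition = matrix(qlogis(c(psi12, psi21)), 1, 2,
                        dimnames = list("(Intercept)", NULL)),
    step = matrix(log(c(mean1, mean2)), 1, 2,
                  dimnames = list("(Intercept)", NULL)),
    log_sd = log(c(sd1, sd2)), logit_zeromass = zeromass,
    angle_mu = mu, angle_kappa = kappa, delta = delta
  )
}

design_const <- hmm_design(pump = FALSE, co2 = FALSE, temp = FALSE)

const_cov <- function(T) {
  data.frame(trial_id = 1, pump_on = 1,
             co2_mgL = 0, temp_C = 20)[rep(1, T), , drop = FALSE]
}

# hand-written emission log density (zero-inflated gamma x von Mises)
oracle_emission <- function(step, angle, mean_k, sd_k, p0_k, mu_k, kappa_k) {
  if (!is.na(step) && step == 0) {
    ls <- log(p0_k)
  } else {
    shape <- (mean_k / sd_k)^2
    ls <- log(1 - p0_k) +
      dgamma(step, shape = shape, scale = sd_k^2 / mean_k, log = TRUE)
  }
  la <- if (is.na(angle)) 0 else {
    kappa_k * cos(angle - mu_k) - log(2 * pi) - log(besselI(kappa_k, 0))
  }
  ls + la
}

# per-path quantities for a single track under intercept-only covariates;
# returns list(loglik, best_path, marginals)
oracle_enumerate <- function(params, d) {
  T <- nrow(d)
  psi12 <- plogis(params$transition["(Intercept)", 1])
  psi21 <- plogis(params$transition["(Intercept)", 2])
  G <- rbind(c(1 - psi12, psi12), c(psi21, 1 - psi21))
  delta <- if (!is.null(params$delta)) params$delta
           else c(psi21, psi12) / (psi12 + psi21)
  means <- exp(params$step["(Intercept)", ])
  sds <- exp(params$log_sd)
  p0 <- plogis(params$logit_zeromass)
  emis <- matrix(0, T, 2)
  for (t in seq_len(T)) for (k in 1:2)
    emis[t, k] <- oracle_emission(d$step_m[t], d$angle_rad[t], means[k],
                                  sds[k], p0[k], params$angle_mu[k],
                                  params$angle_kappa[k])
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))
  lp <- apply(paths, 1, function(s) {
    v <- log(delta[s[1]]) + emis[1, s[1]]
    if (T > 1) for (t in 2:T)
      v <- v + log(G[s[t - 1], s[t]]) + emis[t, s[t]]
    v
  })
  m <- max(lp)
  loglik <- m + log(sum(exp(lp - m)))
  w <- exp(lp - loglik)
  marg1 <- vapply(seq_len(T), function(t) sum(w[paths[, t] == 1]), numeric(1))
  list(loglik = loglik, best_path = paths[which.max(lp), ],
       marginals = marg1)
}
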