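# forward likelihood against closed forms and exhaustive enumeration;
# fitting behavior

test_that("single-observation likelihood equals the mixture closed form", {
  p <- simple_params()
  d <- simulate_step_series(p, const_cov(1), 1, design_const, seed = 3)
  delta <- local({
    psi <- plogis(p$transition["(Intercept)", ])
    c(psi[2], psi[1]) / sum(psi)
  })
  X1 <- matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)"))
  e1 <- step_density(d$step_m, 1, p, X1) * angle_density(d$angle_rad, 1, p)
  e2 <- step_density(d$step_m, 2, p, X1) * angle_density(d$angle_rad, 2, p)
  expect_equal(loglik_forward(p, d, design_const),
               unname(log(delta[1] * e1 + delta[2] * e2)), tolerance = 1e-12)
})

test_that("forward likelihood agrees with exhaustive path enumeration", {
  for (s in 1:4) {
    p <- simple_params(psi12 = 0.1 + 0.1 * s, psi21 = 0.4 - 0.05 * s,
                       kappa = c(0.2, 1 + s / 2))
    d <- simulate_step_series(p, const_cov(8), 1, design_const, seed = 70 + s)
    oracle <- oracle_enumerate(p, d)
    ll <- loglik_forward(p, d, design_const)
    expect_lt(abs(ll - oracle$loglik) / abs(oracle$loglik), 1e-10)
  }
})

test_that("the likelihood is invariant to relabeling the states", {
  p <- simple_params(psi12 = 0.2, psi21 = 0.35, mu = c(0.3, -0.1),
                     kappa = c(0.5, 2), delta = c(0.4, 0.6))
  sw <- hmm_params(
    transition = p$transition[, c(2, 1), drop = FALSE],
    step = p$step[, c(2, 1), drop = FALSE],
    log_sd = p$log_sd[c(2, 1)],
    logit_zeromass = p$logit_zeromass[c(2, 1)],
    angle_mu = p$angle_mu[c(2, 1)], angle_kappa = p$angle_kappa[c(2, 1)],
    delta = p$delta[c(2, 1)])
  d <- simulate_step_series(p, const_cov(60), 2, design_const, seed = 12)
  expect_equal(loglik_forward(p, d, design_const),
               loglik_forward(sw, d, design_const), tolerance = 1e-12)
})

test_that("independent tracks contribute additively", {
  p <- simple_params()
  d <- simulate_step_series(p, const_cov(40), 2, design_const, seed = 15)
  d1 <- d[d$fish_id == unique(d$fish_id)[1], ]
  d2 <- d[d$fish_id == unique(d$fish_id)[2], ]
  expect_equal(loglik_forward(p, d, design_const),
               loglik_forward(p, d1, design_const) +
                 loglik_forward(p, d2, design_const), tolerance = 1e-10)
})

test_that("missing covariates are reported with the offending fish", {
  p <- simple_params()
  d <- simulate_step_series(p, const_cov(10), 1, design_const, seed = 2)
  d$co2_mgL[4] <- NA
  expect_error(loglik_forward(p, d, hmm_design(pump = FALSE, temp = FALSE)),
               class = "carplock_invalid_data")
})

test_that("refitting with the same data and seed is deterministic", {
  p <- simple_params(psi12 = 0.1, psi21 = 0.2, mean1 = 1, mean2 = 0.05,
                     sd1 = 0.8, sd2 = 0.04)
  d <- simulate_step_series(p, const_cov(250), 3, design_const, seed = 44)
  f1 <- fit_hmm(d, design_const, n_restarts = 2, seed = 9, compute_se = FALSE)
  f2 <- fit_hmm(d, design_const, n_restarts = 2, seed = 9, compute_se = FALSE)
  expect_identical(f1$params_hat, f2$params_hat)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("fitted states are ordered exploratory-first with Wald SEs", {
  p <- simple_params(psi12 = 0.1, psi21 = 0.2, mean1 = 1, mean2 = 0.05,
                     sd1 = 0.8, sd2 = 0.04)
  d <- simulate_step_series(p, const_cov(300), 4, design_const, seed = 46)
  fit <- fit_hmm(d, design_const, n_restarts = 2, seed = 5)
  est <- fit$params_hat$step["(Intercept)", ]
  expect_gt(est[1], est[2])  # state 1 carries the larger baseline mean
  expect_true(fit$convergence)
  expect_true(all(fit$se[c("step.state1.(Intercept)",
                           "step.state2.(Intercept)")] > 0))
  tab <- coefficient_table(fit)
  expect_true(all(c("Std. deviation", "Zero mass") %in% tab$parameter))
})

test_that("zero mass is estimated only when zeros are present", {
  p <- simple_params(psi12 = 0.1, psi21 = 0.2, mean1 = 1, mean2 = 0.05,
                     sd1 = 0.8, sd2 = 0.04,
                     zeromass = c(-Inf, qlogis(0.3)))
  d0 <- simulate_step_series(p, const_cov(300), 3, design_const, seed = 48)
  fit0 <- fit_hmm(d0, design_const, n_restarts = 1, seed = 1,
                  compute_se = FALSE)
  expect_gt(sum(d0$step_m == 0), 0)
  pz <- plogis(fit0$params_hat$logit_zeromass)
  expect_lt(abs(pz[2] - 0.3), 0.15)  # zeros live in the short state
  p2 <- simple_params()
  d2 <- simulate_step_series(p2, const_cov(120), 2, design_const, seed = 49)
  fit2 <- fit_hmm(d2, design_const, n_restarts = 1, seed = 1,
                  compute_se = FALSE)
  expect_identical(fit2$params_hat$logit_zeromass, c(-Inf, -Inf))
})
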