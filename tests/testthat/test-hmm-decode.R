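# Viterbi, forward-backward posteriors, time budgets, pseudo-residuals

test_that("Viterbi matches the exhaustive most-probable path", {
  for (s in 1:3) {
    p <- simple_params(psi12 = 0.15 + 0.05 * s, psi21 = 0.3,
                       kappa = c(0.3, 1.5))
    d <- simulate_step_series(p, const_cov(10), 1, design_const,
                              seed = 200 + s)
    oracle <- oracle_enumerate(p, d)
    v <- viterbi(p, d, design_const)
    expect_equal(v$state, unname(oracle$best_path))
  }
})

test_that("with uninformative emissions the path follows the prior", {
  # identical emissions in both states; stay probabilities dominate, and the
  # initial distribution is forced to state 2
  p <- simple_params(psi12 = 0.05, psi21 = 0.05, mean1 = 1, mean2 = 1,
                     sd1 = 0.5, sd2 = 0.5, mu = c(0, 0), kappa = c(1, 1),
                     delta = c(0.05, 0.95))
  d <- simulate_step_series(p, const_cov(30), 1, design_const, seed = 23)
  v <- viterbi(p, d, design_const)
  expect_true(all(v$state == 2))
})

test_that("well-separated states are decoded almost perfectly", {
  p <- simple_params(psi12 = 0.04, psi21 = 0.05, mean1 = 0.988,
                     mean2 = 0.026, sd1 = 0.928, sd2 = 0.019)
  d <- simulate_step_series(p, const_cov(800), 5, design_const, seed = 31)
  v <- viterbi(p, d, design_const)
  expect_gt(mean(v$state == d$state), 0.99)
})

test_that("posteriors are normalized and match enumeration marginals", {
  p <- simple_params(psi12 = 0.25, psi21 = 0.4, kappa = c(0.5, 3))
  d <- simulate_step_series(p, const_cov(6), 1, design_const, seed = 77)
  post <- state_probabilities(p, d, design_const)
  expect_true(all(post$p_state1 >= 0 & post$p_state1 <= 1))
  oracle <- oracle_enumerate(p, d)
  expect_equal(post$p_state1, oracle$marginals, tolerance = 1e-10)
})

test_that("a single-step posterior is the weighted emission mixture", {
  p <- simple_params(delta = c(0.3, 0.7))
  d <- simulate_step_series(p, const_cov(1), 1, design_const, seed = 5)
  X1 <- matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)"))
  e <- c(step_density(d$step_m, 1, p, X1) * angle_density(d$angle_rad, 1, p),
         step_density(d$step_m, 2, p, X1) * angle_density(d$angle_rad, 2, p))
  want <- 0.3 * e[1] / (0.3 * e[1] + 0.7 * e[2])
  post <- state_probabilities(p, d, design_const)
  expect_equal(post$p_state1, want, tolerance = 1e-12)
})

test_that("state time budgets pool step counts over fish", {
  dec <- data.frame(
    fish_id = rep(c("a", "b", "c"), times = c(4000, 4000, 2125)),
    state = rep(2L, 10125))
  dec$state[1:4508] <- 1L
  ex <- data.frame(fish_id = c("a", "b", "c"), time_min = c(10, 95, 30),
                   event = c(1, 0, 1))
  b <- state_time_budget(dec, ex, horizon_min = 90)
  expect_equal(round(100 * b$overall_fraction, 1), 44.5)
  expect_equal(b$n_state1, 4508)
  expect_equal(b$per_fish$fraction_exploratory[1], 4000 / 4000)
  expect_equal(b$per_fish$exit_min, c(10, 90, 30))  # censored -> horizon

  all1 <- data.frame(fish_id = "z", state = rep(1L, 7))
  bz <- state_time_budget(all1, data.frame(fish_id = "z", time_min = 5,
                                           event = 1))
  expect_equal(bz$per_fish$fraction_exploratory, 1)
  expect_error(
    state_time_budget(dec, ex[-2, ]), class = "carplock_missing_exit")
})

test_that("pseudo-residuals are deterministic and zero at the mixture median", {
  p <- simple_params(psi12 = 0.2, psi21 = 0.3, mean1 = 1, mean2 = 0.05,
                     sd1 = 0.8, sd2 = 0.04)
  d <- simulate_step_series(p, const_cov(50), 2, design_const, seed = 91)
  r1 <- pseudo_residuals(p, d, design_const)
  r2 <- pseudo_residuals(p, d, design_const)
  expect_identical(r1, r2)
  expect_true(all(is.na(r1$angle_resid[d$step_index == 1])))

  # put the first observation of a fresh series exactly at the predictive
  # median of the step mixture: its residual must be 0
  delta <- local({
    psi <- plogis(p$transition["(Intercept)", ])
    c(psi[2], psi[1]) / sum(psi)
  })
  mix_cdf <- function(x)
    delta[1] * pgamma(x, shape = (1 / 0.8)^2, scale = 0.8^2 / 1) +
    delta[2] * pgamma(x, shape = (0.05 / 0.04)^2, scale = 0.04^2 / 0.05)
  med <- uniroot(function(x) mix_cdf(x) - 0.5, c(1e-8, 10), tol = 1e-12)$root
  d1 <- d[d$fish_id == d$fish_id[1] & d$step_index == 1, ]
  d1$step_m <- med
  r <- pseudo_residuals(p, d1, design_const)
  expect_equal(r$step_resid, 0, tolerance = 1e-6)
})
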