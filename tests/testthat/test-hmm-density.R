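# transition matrices, emission densities and von Mises utilities

test_that("transition matrices are stochastic and follow the logit link", {
  p0 <- simple_params(psi12 = 0.5, psi21 = 0.5)  # all coefficients zero
  G <- transition_matrix(p0, const_cov(1), ~1)
  expect_equal(G[1, 2], 0.5)
  expect_equal(G[2, 1], 0.5)

  # the exploratory->encamped baseline switching probability at reference
  # covariates equals logistic(-2.2094) ~ 0.0989
  pref <- hmm_params(
    transition = matrix(c(-2.2094, 0), 1, 2, dimnames = list("(Intercept)", NULL)),
    step = matrix(c(0, -1), 1, 2, dimnames = list("(Intercept)", NULL)),
    log_sd = c(0, 0))
  G2 <- transition_matrix(pref, const_cov(1), ~1)
  expect_equal(G2[1, 2], 0.0989, tolerance = 1e-3)

  for (s in 1:5) {
    set.seed(s)
    pr <- simple_params(psi12 = runif(1), psi21 = runif(1))
    G <- transition_matrix(pr, const_cov(1), ~1)
    expect_equal(rowSums(G), c("1" = 1, "2" = 1), tolerance = 1e-12)
    expect_true(all(G >= 0 & G <= 1))
  }
})

test_that("covariates shift the switching probability on the logit scale", {
  p <- hmm_params(
    transition = matrix(c(-2, 0.0096, -1, 0), 2, 2,
                        dimnames = list(c("(Intercept)", "co2_mgL"), NULL)),
    step = matrix(c(0, 0, -1, 0), 2, 2,
                  dimnames = list(c("(Intercept)", "co2_mgL"), NULL)),
    log_sd = c(0, 0))
  f <- ~co2_mgL
  G0 <- transition_matrix(p, data.frame(co2_mgL = 0), f)
  G150 <- transition_matrix(p, data.frame(co2_mgL = 150), f)
  expect_equal(G0[1, 2], plogis(-2))
  expect_equal(G150[1, 2], plogis(-2 + 0.0096 * 150))
  expect_gt(G150[1, 2], G0[1, 2])
})

test_that("step density is a moment-matched zero-inflated gamma", {
  # exploratory-state moments: mean 0.988 m, SD 0.928 m
  p <- simple_params(mean1 = 0.988, sd1 = 0.928,
                     zeromass = c(qlogis(0.1), -Inf))
  X <- matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)"))
  x <- c(0.05, 0.5, 1, 2.5)
  got <- step_density(x, 1, p, X)
  shape <- (0.988 / 0.928)^2
  scale <- 0.928^2 / 0.988
  expect_equal(shape, 1.1335, tolerance = 1e-4)
  expect_equal(scale, 0.8716, tolerance = 1e-4)
  expect_equal(got, 0.9 * dgamma(x, shape = shape, scale = scale),
               tolerance = 1e-12)
  # the point mass is returned exactly at zero
  expect_equal(step_density(0, 1, p, X), 0.1)
  expect_error(step_density(-1, 1, p, X), class = "carplock_invalid_data")
  # log-scale SD link: the reported -0.0745 working value is 0.928 m
  expect_equal(exp(-0.0745), 0.928, tolerance = 1e-3)
})

test_that("von Mises density matches closed forms and is symmetric", {
  p <- simple_params(mu = c(0, 0), kappa = c(0, 1))
  expect_equal(angle_density(c(-3, 0, 2), 1, p), rep(1 / (2 * pi), 3))
  expect_equal(angle_density(0, 2, p), exp(1) / (2 * pi * besselI(1, 0)),
               tolerance = 1e-12)
  expect_equal(angle_density(0, 2, p), 0.3417, tolerance = 1e-4)
  pm <- simple_params(mu = c(0.7, 0), kappa = c(2.3, 1))
  x <- c(0.1, 0.5, 1.9)
  expect_equal(angle_density(0.7 + x, 1, pm), angle_density(0.7 - x, 1, pm))
  bad <- simple_params()
  bad$angle_kappa[1] <- -1
  expect_error(angle_density(0, 1, bad), class = "carplock_invalid_params")
})

test_that("von Mises density integrates to one over the circle", {
  for (kappa in c(0, 0.001, 1, 10)) {
    p <- simple_params(mu = c(0.4, 0), kappa = c(kappa, 1))
    ii <- integrate(function(a) angle_density(a, 1, p), -pi, pi,
                    rel.tol = 1e-10)
    expect_lt(abs(ii$value - 1), 1e-8)
  }
})

test_that("the von Mises CDF matches quadrature and supports sampling", {
  mu <- 0.5; kappa <- 1.7
  qs <- c(-3, -1, 0, 0.5, 2, pi)
  for (q in qs) {
    ref <- integrate(function(a) exp(kappa * cos(a - mu)) /
                       (2 * pi * besselI(kappa, 0)), -pi, q,
                     rel.tol = 1e-10)$value
    expect_equal(pvonmises(q, mu, kappa), ref, tolerance = 1e-6)
  }
  set.seed(8)
  draws <- rvonmises(8000, mu, kappa)
  expect_true(all(draws > -pi & draws <= pi))
  ks <- suppressWarnings(ks.test(draws, function(q) pvonmises(q, mu, kappa)))
  expect_gt(ks$p.value, 0.01)
})
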