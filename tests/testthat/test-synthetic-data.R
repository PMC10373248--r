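# properties of the trial/emission simulators against their generating laws

test_that("simulation is byte-identical under a fixed seed", {
  arena <- lock_arena()
  pr <- make_treatment_profile("pump_co2", horizon_s = 600)
  pp <- default_hmm_params(trial_effects = FALSE)
  s1 <- simulate_trial(arena, pr, pp, n_fish = 2, seed = 99)
  s2 <- simulate_trial(arena, pr, pp, n_fish = 2, seed = 99)
  expect_identical(s1, s2)
  d1 <- simulate_step_series(simple_params(), const_cov(50), 2,
                             design_const, seed = 4)
  d2 <- simulate_step_series(simple_params(), const_cov(50), 2,
                             design_const, seed = 4)
  expect_identical(d1, d2)
})

test_that("with no zero mass and kappa = 0 simulated angles are uniform", {
  p <- simple_params(psi12 = 1e-9, psi21 = 0.999, kappa = c(0, 0),
                     delta = c(1, 0))
  d <- simulate_step_series(p, const_cov(10001), 1, design_const, seed = 21)
  a <- d$angle_rad[!is.na(d$angle_rad)]
  expect_gt(length(a), 9000)
  ks <- suppressWarnings(ks.test(a, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated step moments match the generating gamma in a fixed state", {
  p <- simple_params(psi12 = 1e-9, psi21 = 0.999, mean1 = 0.988, sd1 = 0.928,
                     delta = c(1, 0))
  n <- 10000
  d <- simulate_step_series(p, const_cov(n), 1, design_const, seed = 31)
  expect_true(all(d$state == 1))
  s <- d$step_m
  se_mean <- sd(s) / sqrt(n)
  expect_lt(abs(mean(s) - 0.988), 3 * se_mean)
  m4 <- mean((s - mean(s))^4)
  se_sd <- sqrt(max(m4 - sd(s)^4, 0) / n) / (2 * sd(s))
  expect_lt(abs(sd(s) - 0.928), 3 * se_sd)
})

test_that("empirical transition frequencies match the generating matrix", {
  p <- simple_params(psi12 = 0.12, psi21 = 0.34)
  d <- simulate_step_series(p, const_cov(10000), 1, design_const, seed = 41)
  s <- d$state
  from1 <- which(s[-length(s)] == 1)
  from2 <- which(s[-length(s)] == 2)
  f12 <- mean(s[from1 + 1] == 2)
  f21 <- mean(s[from2 + 1] == 1)
  expect_lt(abs(f12 - 0.12), 3 * sqrt(0.12 * 0.88 / length(from1)))
  expect_lt(abs(f21 - 0.34), 3 * sqrt(0.34 * 0.66 / length(from2)))
})

test_that("zero mass produces exact zero steps at its probability", {
  p <- simple_params(psi12 = 1e-9, psi21 = 0.999, zeromass = c(qlogis(0.2), -Inf),
                     delta = c(1, 0))
  d <- simulate_step_series(p, const_cov(8000), 1, design_const, seed = 51)
  pz <- mean(d$step_m == 0)
  expect_lt(abs(pz - 0.2), 3 * sqrt(0.2 * 0.8 / 8000))
  # zero steps and their successors carry no defined turning angle
  z <- which(d$step_m == 0)
  expect_true(all(is.na(d$angle_rad[z])))
  expect_true(all(is.na(d$angle_rad[pmin(z + 1, nrow(d))])))
})

test_that("simulated positions before exit stay inside the arena", {
  arena <- lock_arena()
  pr <- make_treatment_profile("pump_only", horizon_s = 1800)
  pp <- default_hmm_params(trial_effects = FALSE)
  tr <- simulate_trial(arena, pr, pp, n_fish = 4, seed = 7)
  for (f in tr$fish) {
    path <- f$path
    inside <- seq_len(nrow(path) - as.integer(!f$truth$censored))
    expect_true(all(path$x_m[inside] >= 0 & path$x_m[inside] <= arena$length))
    expect_true(all(path$y_m[inside] >= 0 & path$y_m[inside] <= arena$width))
    expect_equal(length(f$truth$state_sequence), nrow(path) - 1L)
  }
})

test_that("strong gate-ward drift makes every fish exit before the horizon", {
  arena <- lock_arena()
  pr <- make_treatment_profile("null", horizon_s = 5400)
  # pure exploratory state, long straight steps (huge concentration, mu = 0)
  p <- simple_params(psi12 = 1e-9, psi21 = 0.999, mean1 = 5, sd1 = 1,
                     mu = c(0, 0), kappa = c(5000, 5000), delta = c(1, 0))
  tr <- simulate_trial(arena, pr, p, n_fish = 5, seed = 13,
                       design = design_const)
  expect_true(all(!vapply(tr$fish, function(f) f$truth$censored, logical(1))))
  ex <- vapply(tr$fish, function(f) f$truth$exit_time_s, numeric(1))
  expect_true(all(ex > 0 & ex < 5400))
})

test_that("position noise reproduces the positioning system's median error", {
  arena <- lock_arena(length = 1e6, width = 1e6, gate_x = 1e6)  # no walls
  pr <- make_treatment_profile("null", horizon_s = 3600)
  p <- simple_params(psi12 = 1e-9, psi21 = 0.999, mean1 = 0.5, sd1 = 0.3,
                     delta = c(1, 0))
  set.seed(61)
  tr <- simulate_trial(arena, pr, p, n_fish = 10, design = design_const)
  errs <- unlist(lapply(tr$fish, function(f) {
    tru_x <- approx(f$path$t_s, f$path$x_m, xout = f$fixes$t_s)$y
    tru_y <- approx(f$path$t_s, f$path$y_m, xout = f$fixes$t_s)$y
    c(abs(f$fixes$x_m - tru_x), abs(f$fixes$y_m - tru_y))
  }))
  # median per-axis absolute error of N(0, 1.4826 * 0.878) is 0.878 m
  expect_gt(length(errs), 5000)
  expect_lt(abs(median(errs) - 0.878), 0.05)
})

test_that("inter-fix gaps respect the transmitter pulse-rate range", {
  arena <- lock_arena()
  pr <- make_treatment_profile("null", horizon_s = 1200)
  pp <- default_hmm_params(trial_effects = FALSE)
  tr <- simulate_trial(arena, pr, pp, n_fish = 2, seed = 3)
  for (f in tr$fish) {
    g <- diff(f$fixes$t_s)
    expect_true(all(g >= 1.301 - 1e-9 & g <= 5.862 + 1e-9))
  }
})

test_that("fixtures round-trip through write and read", {
  arena <- lock_arena()
  pr <- make_treatment_profile("pump_co2", horizon_s = 600)
  pp <- default_hmm_params(trial_effects = FALSE)
  tr <- simulate_trial(arena, pr, pp, n_fish = 3, seed = 17, trial_id = 8)
  dir <- withr::local_tempdir()
  mf <- write_fixtures(list(tr), dir)
  files <- list.files(dir)
  expect_length(grep("^fixes_", files), 3)
  expect_length(grep("^covariates_", files), 1)
  expect_length(grep("^truth_", files), 1)
  expect_true("manifest.json" %in% files)
  back <- read_fixtures(dir)
  expect_length(back, 1)
  expect_equal(back[["8"]]$treatment, "pump_co2")
  expect_equal(back[["8"]]$fixes[[1]], tr$fish[[1]]$fixes,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back[["8"]]$covariates, tr$covariates,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back[["8"]]$truth$state[back[["8"]]$truth$fish_id == "T8_F2"],
               tr$fish[[2]]$truth$state_sequence)
})

test_that("degenerate simulator inputs are rejected", {
  arena <- lock_arena()
  pr <- make_treatment_profile("null", horizon_s = 600)
  pp <- default_hmm_params(trial_effects = FALSE)
  expect_error(simulate_trial(arena, pr, pp, n_fish = 0),
               class = "carplock_invalid_data")
  expect_error(write_fixtures(list(), tempdir()),
               class = "carplock_invalid_data")
})
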