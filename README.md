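# carplock

Movement analysis of acoustic-tagged invasive carp responding to
carbon-dioxide and forced-water-circulation deterrents inside a navigation
lock.

## The problem

Navigation locks are pinch points where invasive carp can be blocked or
expelled. In the experiment this package models, tagged common carp were
confined in a ~52 m x 11 m lock chamber, exposed to one of three treatments
(CO₂ injection with forced water circulation, circulation only, or nothing),
and tracked with a sub-meter acoustic positioning array while the downstream
gate stood open. Two questions drive the analysis: *how quickly do carp
leave the lock under each treatment*, and *which fine-scale behavioral
changes produce those differences*?

`carplock` re-implements that analysis as a tested, reusable pipeline and
pairs it with a synthetic-trial generator with known ground truth, so every
stage can be validated end-to-end:

1. **Track regularization.** Transmitters fire irregularly (1.3–5.9 s
   apart). A continuous-time correlated random walk — integrated
   Ornstein–Uhlenbeck velocity with parameters (β, σ, τ):
   velocity mean-reverts to 0 at rate β, is driven by white noise of
   intensity σ, and fixes carry Gaussian measurement error τ — is fit by
   exact Kalman-filter maximum likelihood, and the smoother predicts
   positions every 6 s (`fit_ctcrw()`, `predict_regular()`).
2. **Step lengths and turning angles.** From the regular track,
   `steps_and_angles()` computes step lengths (m per 6 s) and signed turning
   angles in (−π, π], joined with per-step treatment covariates.
3. **Two-state hidden Markov model.** States are *exploratory* (long steps,
   near-uniform turning) and *encamped* (short steps). Step lengths follow a
   zero-inflated gamma whose log mean is linear in trial, circulation
   (pump off vs on), CO₂ concentration, and temperature:
   log λₖ = θ₀ₖ + θ₁R + θ₂P + θ₃CO₂ + θ₄T; turning angles are von Mises.
   Transition probabilities use the multinomial-logit link
   logit ψᵢ→ⱼ = β₀ + β₂R + β₃P + β₄CO₂ + β₅T. Fitting maximizes the
   forward-algorithm likelihood (`fit_hmm()`); `viterbi()`,
   `state_probabilities()` and `pseudo_residuals()` decode states and check
   fit; `state_time_budget()` summarizes the fraction of time spent
   exploratory against exit times.
4. **Time to exit.** `detect_exit()` interpolates the gate crossing;
   `km_estimate()` computes the Kaplan–Meier product-limit survival curve
   S(t) = Π (1 − dᵢ/nᵢ) with Greenwood standard errors under right
   censoring at the 90-min horizon; `median_exit()` and
   `remaining_proportion()` give the study's summary statistics.
5. **Orchestration.** `run_pipeline()` runs
   simulate → regularize → extract → fit → decode → summarize from a single
   YAML/JSON config, writing every intermediate table plus a reproducible
   JSON report (`validate_config()` checks the schema; a thin CLI wrapper
   lives at `inst/scripts/carplock-pipeline.R`).

The simulator (`simulate_trial()`, `simulate_step_series()`) emulates the
study design: the 20-trial roster (`study_roster()`), CO₂ ramps to
100–150 mg/L over 5–10 min, irregular fix gaps over the transmitter
pulse-rate range, positioning noise calibrated to the array's 0.878 m
median error, and two-state switching movement with reflecting walls and an
absorbing gate, using the study-scale coefficient table
(`default_hmm_params()`) as ground truth.

## Worked example

```r
library(carplock)

design <- hmm_design(pump = FALSE, co2 = FALSE, temp = FALSE)
truth <- hmm_params(
  transition = matrix(qlogis(c(0.10, 0.15)), 1, 2,
                      dimnames = list("(Intercept)", NULL)),
  step = matrix(log(c(0.988, 0.026)), 1, 2,
                dimnames = list("(Intercept)", NULL)),
  log_sd = log(c(0.928, 0.019)),
  angle_mu = c(pi, 0), angle_kappa = c(0.00002, 0.0009))
covs <- data.frame(trial_id = 1, pump_on = 1, co2_mgL = 0,
                   temp_C = 21)[rep(1, 600), ]
obs <- simulate_step_series(truth, covs, n_tracks = 8, design = design,
                            seed = 3)
fit <- fit_hmm(obs, design, n_restarts = 2, seed = 1)
fit
#> Two-state movement HMM fit: 4800 steps in 8 tracks, loglik -7684.15
#> Two-state movement HMM parameters
#>   baseline mean step: state1 (exploratory) 0.981 m, state2 (encamped) 0.026 m
#>   step SD: 0.924, 0.019 m; zero mass: 0, 0
#>   ...
```

The fitted baseline step means (0.981 m and 0.026 m here) recover the
generating values 0.988 m and 0.026 m; state 1 is always the long-step
"exploratory" state by the package's ordering rule. Decoding and the
survival summaries follow the same pattern:

```r
dec <- viterbi(fit$params_hat, obs, design)
mean(dec$state == obs$state)      # 0.981: per-step decoding accuracy

exits <- data.frame(fish_id = unique(obs$fish_id),
                    time_min = c(4, 12, 90, 7, 22, 90, 16, 9),
                    event = c(1, 1, 0, 1, 1, 0, 1, 1))
km_estimate(exits)
#> Kaplan-Meier time-to-exit: n = 8, 6 events; median 12.0 min
median_exit(exits, horizon_min = 90)$median_min   # 14 (censored -> 90 min)
remaining_proportion(2, 8)        # 25% remaining, SE 15.3%
```

A full synthetic experiment runs from a config:

```r
report <- run_pipeline(list(seed = 42, output_dir = "out",
                            hmm = list(n_restarts = 2)))
```

which writes `out/sim/` (fix/covariate/truth fixtures), `tracks.csv`,
`steps.csv`, `coefficients.csv` (the four-column coefficient layout),
`decoded.csv`, `residuals.csv`, `exits.csv`, per-treatment `km_*.csv`,
`budgets.csv` and `report.json`.

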