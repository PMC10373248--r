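---
title: "Methods: movement states and time-to-exit of carp under lock deterrents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement states and time-to-exit of carp under lock deterrents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`carplock` analyzes fine-scale acoustic telemetry of carp confined in a
navigation lock under deterrent treatments (CO₂ plus forced water
circulation, circulation only, or neither). This vignette is the package's
account of the models it implements, the choices made where the design was
genuinely open, and what the synthetic-data checks do and do not establish.

## Track regularization: the CTCRW model

Transmitters emit at irregular 1.3–5.9 s intervals, while the movement model
needs positions on a fixed 6-s grid. Each coordinate axis is modeled as an
integrated Ornstein–Uhlenbeck process: velocity $v(t)$ mean-reverts to zero
at rate $\beta$ (1/s) under white noise of intensity $\sigma$; position is
its integral; an observed fix adds Gaussian error with SD $\tau$ (m). The
two axes share parameters — the lock chamber has no privileged horizontal
direction at the scale of a few seconds. Exact discrete-time transition
moments over each inter-fix gap drive a Kalman filter (the likelihood, in
compiled code) and an RTS smoother (the 6-s predictions, with prediction
SEs). The grid is anchored at the first fix and never extends past the last
one: no positions are invented beyond the data's support.

Numerical choices: optimization is quasi-Newton (BFGS) on
$(\log\beta, \log\sigma, \log\tau)$ with three deterministic starts (a
data-driven heuristic and two fixed offsets) to guard against local optima;
the filter is initialized at the first fix with a diffuse position variance
($10^4$ m²) and the stationary velocity variance $\sigma^2/2\beta$. A
noise-free constant-velocity track drives $\hat\tau$ below $10^{-3}$ m, and
the smoother reproduces exact data to machine precision — both are tested.

A single smoothed track feeds the downstream model. Propagating positional
uncertainty by multiple imputation (drawing several tracks from the
smoother) would be a natural extension; it is deliberately out of scope, and
the consequences are visible in the pipeline results (see *Limitations*).

Identifiability caveat: with measurement noise around 1.3 m and fixes a few
seconds apart, the fine-scale velocity parameters $(\beta, \sigma)$ are only
weakly identified — displacement between fixes is dominated by noise. The
parameter-recovery check therefore runs at $\tau = 0.3$ m, $\beta = 0.6$/s,
$\sigma = 0.4$ with $n = 2000$ fixes, a regime where all three parameters
are estimable; at $\tau \approx 1.3$ m relative errors above 15% persist
even at much larger $n$ because the information is simply not in the data.

## The two-state movement HMM

Observations are step lengths $\ell_t$ (m per 6 s) and turning angles
$\phi_t \in (-\pi, \pi]$, with a latent two-state chain: state 1
"exploratory" (long steps, diffuse turning), state 2 "encamped" (short
steps). The emission model per state $k$:

* **Step length**: a zero-inflated gamma. With probability
  $p_{0k} = \mathrm{logit}^{-1}(z_k)$ the step is exactly 0 (a stationary
  fix); otherwise gamma with mean
  $\lambda_{kt} = \exp(\theta_{0k} + \theta_1 R + \theta_2 P + \theta_3
  \mathrm{CO_2}_t + \theta_4 T)$ and SD $s_k = \exp(w_k)$, moment-matched to
  shape $\lambda^2/s^2$ and scale $s^2/\lambda$. Covariates: trial $R$
  (factor, reference = first trial), pump-off indicator $P$ (reference =
  pump on), CO₂ in mg/L (time-varying within trial), and the trial-mean
  water temperature in °C.
* **Turning angle**: von Mises$(\mu_k, \kappa_k)$, covariate-free. Angles
  are undefined for the first step of a track and next to zero-length steps;
  such steps contribute an emission factor of 1.

Transition probabilities use the two-state multinomial-logit link,
$\mathrm{logit}\,\psi_{i\to j, t} = \beta_{0,ij} + \beta_2 R + \beta_3 P +
\beta_4 \mathrm{CO_2}_t + \beta_5 T$, evaluated at the covariates of the
step being left (the same "step start" convention used when joining
covariates to steps). The log-scale links are confirmed internally: the
working SD value $-0.0745$ for the exploratory state exponentiates to the
0.928 m SD reported on the natural scale.

The likelihood is the scaled forward recursion over independent fish-tracks
(compiled); it is verified against exhaustive enumeration of all $2^T$ state
paths for $T \le 10$ to $10^{-10}$ relative error. The initial distribution
defaults to the stationary distribution of the transition matrix at each
track's first-step covariates, with free estimation behind a flag
(`estimate_delta`) — the stationary default is the common choice when tracks
start at an arbitrary point of ongoing behavior.

Fitting and numerics:

* Working scale: logit/log/logit for transition coefficients, step mean and
  SD, zero mass; unconstrained mean direction (wrapped afterwards) and
  $\log\kappa$ for angles.
* The zero-mass parameters are estimated only when the data contain exact
  zeros; otherwise the point mass is fixed at probability 0. Estimating a
  logit with no zeros in the data would push the working parameter to
  $-\infty$ without changing the fit.
* Optimization: BFGS with up to 5 restarts (first a data-driven start that
  splits steps at the median; the rest seeded Gaussian perturbations),
  relative log-likelihood tolerance $10^{-9}$.
* Label switching is resolved after fitting: state 1 is the state with the
  larger baseline (intercept) mean step. Standard errors come from the
  numerically differentiated observed information at the optimum.
* Degenerate working values (overflowing gamma shapes, vanishing mixture
  likelihoods) evaluate to a large penalty rather than an error, so restarts
  recover from bad regions.

Decoding uses Viterbi (ties broken toward the exploratory state) for the
reported time budgets, with forward–backward posteriors available and a
0.5-posterior threshold as an alternative budget definition; whether the
original analysis used Viterbi or posterior thresholding is not stated, and
at the separation of these states the two rarely disagree. Goodness of fit
uses one-step-ahead pseudo-residuals
$z_t = \Phi^{-1}(F(y_t \mid y_{1:t-1}))$, mixing state-conditional CDFs by
forward-predictive weights; the angle CDF is measured from $-\pi$ and
computed by trapezoid quadrature on a 4096-point grid (error well below the
$10^{-6}$ that matters here). Under the generating model both residual
streams are standard normal; the calibration test checks mean within 0.05
of 0 and SD within 0.05 of 1 at 5,000 steps.

One documented inconsistency in the source coefficient table: the encamped
"Std. deviation" working value $-1.665$ exponentiates to 0.189 m, while the
narrative reports 0.019 m for that state. The package follows the log-link
convention everywhere (so the default encamped SD is 0.189 m); tests that
need a coherent, well-separated pair use the narrative values
(0.988/0.928 m and 0.026/0.019 m) explicitly.

## Time to exit

"Survival" is remaining inside the lock. Exit is the first time a track's
x-coordinate reaches the gate line, linearly interpolated between the
bracketing 6-s positions (snapping to the grid would quantize times by
0.1 min for no benefit); fish that never cross are right-censored at the
90-min horizon. The Kaplan–Meier product-limit estimator with Greenwood
standard errors comes from the survival package behind the `km_estimate()`
surface; events precede censorings at tied times. Two medians are reported:
the study's convention (sample median after setting censored fish to the
horizon) and the KM median (first time survival reaches 0.5). The
proportion remaining carries a binomial SE on the percent scale,
$100\sqrt{\hat p(1-\hat p)/n}$.

## What the simulator emulates — and what it does not

`simulate_trial()` generates ground-truth-known trials: the 20-trial roster
(12 CO₂, 6 circulation-only, 2 null; 2–3 fish each), CO₂ ramping linearly
to 100–150 mg/L over 5–10 min (defaults 125 mg/L, 7.5 min — the midpoints
of the reported ranges) then held, pumps on from gate opening, constant
within-trial temperature (defaults spread deterministically over
20.5–23.5 °C so the covariate is informative), a 51.82 m × 11.12 m arena
whose downstream wall is the open gate, step-turn kinematics (heading plus
turning angle), specular wall reflection, an absorbing gate, uniform fix
gaps over 1.301–5.862 s, and isotropic Gaussian positioning noise with SD
$1.4826 \times 0.878 \approx 1.30$ m so the median per-axis absolute error
equals the array's measured 0.878 m. Start positions are uniform over the
upstream two-thirds of the arena (the protocol does not state where carp
were when the gate opened). Latent states evolve per 6-s step with the
transition matrix at the step-start covariates — exactly the convention the
likelihood assumes, which is what makes exact recovery tests possible.

Two realism gaps matter for interpretation. First, near-uniform turning
angles make simulated exploratory movement a diffusive random walk, whereas
real carp that "explore" their way out of a lock move more directedly;
simulated exit rates are therefore much lower than the field study's (most
synthetic fish are censored at 90 min), and synthetic Kaplan–Meier curves
should be read as a correctness exercise, not a behavioral prediction.
Second, with 1.3 m positioning noise on 6-s steps of 0.03–1 m, the single
smoothed track attenuates true step lengths and blurs the encamped state;
the pipeline's fitted baseline means on fully synthetic noisy data are
biased accordingly (the original analysis faced the same trade-off). The
HMM recovery tests therefore simulate at the step-series level, where the
observation model is exact; the pipeline run demonstrates that the stages
compose, not that smoothing is unbiased.

## Problem sizes and seeds

The test suite and `scripts/acceptance.R` use sizes chosen to make
Monte-Carlo checks sharp while staying desk-scale: enumeration oracles at
$T \le 10$; distributional properties at $n = 10{,}000$ draws (3 Monte-Carlo
SEs); state-mean recovery at 30 tracks × 900 steps (errors under 1%,
asserted at 5%); CO₂ sign recovery over 20 seeded replicates of 6 tracks ×
600 steps with a 0→150 mg/L ramp; CTCRW recovery at 2,000 fixes; residual
calibration at 5,000 steps; the full pipeline on the 20-trial roster at the
90-min horizon. Every stochastic quantity derives from an explicit seed;
rerunning any configuration reproduces its report byte-for-byte.

## Known limitations

* Two states only, no covariates on turning angles, no random effects —
  matching the scope of the original analysis.
* Single-imputation regularization (no propagation of smoother uncertainty
  into the HMM).
* The CTCRW assumes shared isotropic dynamics and measurement error;
  hydrophone-geometry-dependent error is not modeled.
* The simulator's movement rules (reflection, absorbing full-width gate,
  uniform starts) are package conventions where the protocol is silent, not
  observed mechanics.
* No between-treatment hypothesis tests (log-rank, Cox): the source
  analysis reported descriptive KM summaries only.
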