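#' Default covariate design for the movement HMM
#'
#' Both the transition logits and the log mean step lengths are linear in the
#' same covariates: trial (factor, reference = first trial), pump off
#' (indicator, reference = pump on), CO2 concentration (mg/L) and water
#' temperature (degrees C). \code{hmm_design()} builds the two model formulas;
#' trial effects can be dropped for small designs.
#'
#' @param trial logical: include per-trial factor effects.
#' @param pump,co2,temp logical: include the respective covariate.
#' @return list with elements \code{transition} and \code{step}, each a
#'   one-sided formula.
#' @export
hmm_design <- function(trial = FALSE, pump = TRUE, co2 = TRUE, temp = TRUE) {
  terms <- c(if (trial) "trial", if (pump) "pump_off", if (co2) "co2_mgL",
             if (temp) "temp_C")
  f <- if (length(terms)) {
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  } else {
    ~1
  }
  list(transition = f, step = f)
}

# model matrix for one formula over a step-angle table; adds the derived
# trial factor (levels in numeric trial order) and pump_off indicator
design_matrix <- function(data, formula) {
  df <- as.data.frame(data)
  if (!is.null(df$trial_id)) {
    ids <- unique(df$trial_id)
    ord <- if (!anyNA(suppressWarnings(as.numeric(ids)))) {
      as.character(sort(as.numeric(ids)))
    } else sort(as.character(ids))
    df$trial <- factor(as.character(df$trial_id), levels = ord)
  }
  if (!is.null(df$pump_on)) df$pump_off <- 1 - df$pump_on
  vars <- all.vars(formula)
  missing <- setdiff(vars, names(df))
  if (length(missing))
    abort(paste0("design covariates not found in data: ",
                 paste(missing, collapse = ", ")), "carplock_design_error")
  if (anyNA(df[vars]))
    abort("design covariates contain missing values", "carplock_design_error")
  model.matrix(formula, df)
}

# align a model matrix to a coefficient rowname set, by name
align_design <- function(X, coef_names, what) {
  missing <- setdiff(coef_names, colnames(X))
  if (length(missing))
    abort(paste0("covariate columns required by ", what, " coefficients are ",
                 "absent from the design: ", paste(missing, collapse = ", ")),
          "carplock_design_error")
  X[, coef_names, drop = FALSE]
}

#' Per-step transition probabilities
#'
#' Evaluates the two off-diagonal switching probabilities of the two-state
#' chain at each row of a covariate design matrix: psi_ij =
#' logistic(x' beta_ij) for the ordered pairs 1->2 and 2->1.
#'
#' @param params an \code{hmm_params} object (only \code{$transition} used).
#' @param X design matrix whose columns cover the coefficient rownames.
#' @return numeric matrix (nrow(X) x 2) with columns \code{1to2},
#'   \code{2to1}.
#' @export
transition_probs <- function(params, X) {
  B <- params$transition
  X <- align_design(as.matrix(X), rownames(B), "transition")
  psi <- plogis(X %*% B)
  colnames(psi) <- colnames(B)
  psi
}

#' Transition matrix at one covariate setting
#'
#' @param params an \code{hmm_params} object.
#' @param covariates single-row data.frame (or list) with the covariates the
#'   design needs (e.g. \code{trial_id}, \code{pump_on}, \code{co2_mgL},
#'   \code{temp_C}), or an already-built single-row design matrix.
#' @param formula design formula; ignored when \code{covariates} is a matrix.
#' @return 2x2 stochastic matrix; rows index the current state.
#' @examples
#' p <- default_hmm_params(trial_effects = FALSE)
#' transition_matrix(p, data.frame(pump_on = 1, co2_mgL = 0, temp_C = 0))
#' @export
transition_matrix <- function(params, covariates,
                              formula = hmm_design()$transition) {
  X <- if (is.matrix(covariates)) covariates
       else design_matrix(as.data.frame(covariates), formula)
  if (nrow(X) != 1L)
    abort("`covariates` must describe a single time point", "carplock_design_error")
  psi <- transition_probs(params, X)
  G <- rbind(c(1 - psi[1, 1], psi[1, 1]),
             c(psi[1, 2], 1 - psi[1, 2]))
  dimnames(G) <- list(c("1", "2"), c("1", "2"))
  G
}

# stationary distribution of a 2-state chain from its off-diagonals
stationary_delta <- function(psi12, psi21) {
  s <- psi12 + psi21
  if (s < 1e-300) return(c(0.5, 0.5))
  c(psi21, psi12) / s
}

#' State-dependent step-length density
#'
#' Zero-inflated gamma: a point mass p0 at step length exactly 0, otherwise a
#' gamma density with mean exp(x' theta_k) and standard deviation
#' exp(log_sd_k), moment-matched to shape = mean^2/sd^2 and
#' scale = sd^2/mean.
#'
#' @param step_m numeric vector of step lengths (m, >= 0; NA allowed).
#' @param state state index (1 or 2).
#' @param params an \code{hmm_params} object.
#' @param X design matrix (one row per step, or a single row recycled).
#' @param log logical: return log density.
#' @return numeric vector of (log) density values; NA steps give 1 (or 0).
#' @export
step_density <- function(step_m, state, params, X, log = FALSE) {
  if (any(step_m < 0, na.rm = TRUE))
    abort("step lengths must be nonnegative", "carplock_invalid_data")
  X <- align_design(as.matrix(X), rownames(params$step), "step")
  if (nrow(X) == 1L && length(step_m) > 1L)
    X <- X[rep(1L, length(step_m)), , drop = FALSE]
  m <- exp(drop(X %*% params$step[, state]))
  s <- exp(params$log_sd[state])
  p0 <- plogis(params$logit_zeromass[state])
  shape <- (m / s)^2
  scale <- s^2 / m
  ld <- log1p(-p0) + dgamma(step_m, shape = shape, scale = scale, log = TRUE)
  zero <- !is.na(step_m) & step_m == 0
  ld[zero] <- log(p0)
  ld[is.na(step_m)] <- 0
  if (log) ld else exp(ld)
}

#' von Mises turning-angle density
#'
#' f(phi) = exp(kappa cos(phi - mu)) / (2 pi I0(kappa)); kappa = 0 gives the
#' uniform density 1/(2 pi). Missing angles (first step of a track, or steps
#' adjacent to a zero-length step) contribute a factor of 1.
#'
#' @param angle_rad numeric vector of angles in radians (NA allowed).
#' @param state state index (1 or 2).
#' @param params an \code{hmm_params} object (uses \code{angle_mu},
#'   \code{angle_kappa}).
#' @param log logical: return log density.
#' @return numeric vector of (log) density values.
#' @export
angle_density <- function(angle_rad, state, params, log = FALSE) {
  mu <- params$angle_mu[state]
  kappa <- params$angle_kappa[state]
  if (is.na(kappa) || kappa < 0)
    abort("von Mises concentration must be >= 0", "carplock_invalid_params")
  # exponentially scaled Bessel keeps this finite for large kappa
  ld <- kappa * (cos(angle_rad - mu) - 1) -
    log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
  ld[is.na(angle_rad)] <- 0
  if (log) ld else exp(ld)
}

#' von Mises cumulative distribution measured from -pi
#'
#' P(angle <= q) for angle ~ von Mises(mu, kappa) on (-pi, pi], computed by
#' trapezoid quadrature on a fine fixed grid (absolute error well below
#' 1e-7), which is ample for pseudo-residual work.
#'
#' @param q numeric vector of angles in (-pi, pi].
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return numeric vector of probabilities.
#' @export
pvonmises <- function(q, mu, kappa) {
  n_grid <- 4096L
  g <- seq(-pi, pi, length.out = n_grid + 1L)
  d <- exp(kappa * (cos(g - mu) - 1))
  cw <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * diff(g)))
  cw <- cw / cw[length(cw)]
  out <- approx(g, cw, xout = q, rule = 2)$y
  pmin(pmax(out, 0), 1)
}

#' Draw von Mises turning angles
#'
#' Best-Fisher (1979) wrapped-Cauchy rejection sampler; for very small kappa
#' the distribution is effectively uniform and is sampled directly.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) abort("kappa must be >= 0", "carplock_invalid_params")
  if (kappa < 1e-6) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_angle(out + mu)
}
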