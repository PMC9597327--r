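#' Multiplicative log-normal measurement-noise model
#'
#' All observables are strictly positive, so noise is modelled as
#' mean-unbiased multiplicative log-normal perturbation parameterized by
#' the relative standard deviation on the natural scale. Defaults reflect
#' the replicate spread seen in flat-panel experiments (on the order of
#' 15-20% between biological replicates, dominated by the quota chain).
#'
#' @param sd_X,sd_N,sd_Q Relative standard deviations for biomass, medium
#'   nitrogen and quota observations.
#' @param seed Integer seed; generation is bit-reproducible given the
#'   seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_X = 0.05, sd_N = 0.05, sd_Q = 0.1, seed = 1L) {
  stopifnot(sd_X >= 0, sd_N >= 0, sd_Q >= 0)
  structure(list(sd_X = sd_X, sd_N = sd_N, sd_Q = sd_Q,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Mean-unbiased log-normal factor with relative sd `cv`.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a synthetic replicated observation set
#'
#' Simulates the true trajectory under the given parameters, samples it at
#' the requested days and applies independent multiplicative noise per
#' replicate and variable. Two quota modes mirror the two ways a quota
#' can be obtained in practice: `"direct"` perturbs the simulated quota
#' itself; `"depletion"` re-derives it from the *noisy* nitrogen and
#' biomass observations through the depletion balance
#' `Q = (N0 - N)/X`, propagating the measurement chain (such quotas can
#' mildly exceed `Q_max` under noise; they are flagged via the
#' `quota_exceeds_Qmax` attribute, not clipped). Noisy nitrogen is capped
#' at `N0` (the medium cannot gain nitrogen).
#'
#' @param p A [kinetic_parameters()] (the "true" model).
#' @param initial A [culture_state()].
#' @param reactor A [reactor_config()].
#' @param schedule A [light_schedule()]; defaults to the reactor's
#'   photoperiod.
#' @param days Sampling days (must lie within `duration`).
#' @param m Number of replicates.
#' @param noise A [noise_model()].
#' @param duration Simulation length, days; defaults to the last sampling
#'   day.
#' @param quota_mode `"direct"` or `"depletion"`.
#' @param dt_out,rtol,atol Passed to [simulate_batch()].
#' @return An [observation_set()]; its `truth` attribute stores the
#'   noiseless sampled trajectory.
#' @examples
#' sc <- scenario("5L_flat_panel_4xf2")
#' obs <- generate_observations(kinetic_parameters(), sc$initial,
#'                              sc$reactor, sc$schedule,
#'                              days = c(4, 6, 8, 10, 12, 14, 16), m = 3,
#'                              noise = noise_model(seed = 42))
#' @export
generate_observations <- function(p, initial, reactor, schedule = NULL,
                                  days, m = 3, noise = noise_model(),
                                  duration = max(days),
                                  quota_mode = c("direct", "depletion"),
                                  dt_out = 0.02, rtol = 1e-8, atol = 1e-10) {
  quota_mode <- match.arg(quota_mode)
  if (is.null(schedule)) schedule <- light_schedule(reactor$photoperiod_light_h)
  if (any(days < 0) || any(days > duration))
    stop("sampling days must lie within [0, duration]")
  res <- simulate_batch(initial, reactor, schedule, p, duration = duration,
                        dt_out = dt_out, rtol = rtol, atol = atol)
  idx <- vapply(days, function(d) which.min(abs(res$t - d)), integer(1))
  truth <- data.frame(day = days, X = res$X[idx], N = res$N[idx],
                      Q = res$Q[idx])
  N0 <- initial$N
  set.seed(noise$seed)
  nd <- length(days)
  rep_id <- rep(seq_len(m), each = nd)
  day_rep <- rep(days, times = m)
  X_obs <- rep(truth$X, m) * lognormal_factor(nd * m, noise$sd_X)
  N_obs <- pmin(rep(truth$N, m) * lognormal_factor(nd * m, noise$sd_N), N0)
  Q_obs <- if (quota_mode == "direct")
    rep(truth$Q, m) * lognormal_factor(nd * m, noise$sd_Q)
  else
    quota_from_depletion(N0, N_obs, X_obs)
  d <- data.frame(
    day = rep(day_rep, 3), replicate = rep(rep_id, 3),
    variable = rep(c("X", "N", "Q"), each = nd * m),
    value = c(X_obs, N_obs, Q_obs))
  d <- d[order(d$replicate, d$variable, d$day), ]
  rownames(d) <- NULL
  obs <- observation_set(d, nitrogen_N0 = N0, reactor_id = reactor$geometry)
  attr(obs, "truth") <- truth
  attr(obs, "quota_exceeds_Qmax") <-
    any(d$value[d$variable == "Q"] > p$Q_max)
  obs
}
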