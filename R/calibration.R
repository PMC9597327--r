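#' Medium nitrogen concentration from UV absorbance
#'
#' Standard nitrate determination by second-derivative-free UV
#' spectrophotometry: `N = (14/62) * DF * (ABS220 - 2 ABS275) / 0.06007`,
#' where 14 and 62 are the molecular weights of nitrogen and nitrate and
#' 0.06007 the nitrate calibration factor. The 275 nm reading corrects
#' for dissolved organic matter; when `ABS220 < 2 ABS275` the correction
#' dominates (excessive interference) and the result is floored at zero
#' with a warning.
#'
#' @param ABS220,ABS275 Absorbances at 220 and 275 nm.
#' @param DF Dilution factor applied before measurement.
#' @return Nitrogen concentration, mg N L^-1 (non-negative).
#' @examples
#' nitrate_to_nitrogen(0.3, 0.05, 1)
#' @export
nitrate_to_nitrogen <- function(ABS220, ABS275, DF = 1) {
  stopifnot(DF > 0)
  raw <- (14 / 62) * DF * (ABS220 - 2 * ABS275) / 0.06007
  if (any(raw < 0)) {
    warning("ABS220 < 2*ABS275: organic-matter interference; flooring at 0")
    raw <- pmax(raw, 0)
  }
  raw
}

#' Nitrogen quota from medium depletion
#'
#' Mass-balance estimate of the intracellular quota:
#' `Q = (N0 - N) / DCW` — all nitrogen lost from the medium is assumed to
#' reside in the biomass.
#'
#' @param N0 Initial medium nitrogen, mg N L^-1.
#' @param N Current medium nitrogen, mg N L^-1 (must not exceed `N0`).
#' @param DCW Biomass concentration, mg L^-1 (> 0).
#' @return Quota, mg N mg^-1 DCW.
#' @examples
#' quota_from_depletion(49.3, 10, 400)
#' @export
quota_from_depletion <- function(N0, N, DCW) {
  if (any(DCW <= 0)) stop("DCW must be strictly positive")
  if (any(N > N0 + 1e-12))
    stop("N exceeds N0: uptake cannot be negative")
  (N0 - N) / DCW
}

#' Absorption coefficient from optical density
#'
#' `Ka = ABS550 / (0.01 * DCW)` for a 10 mm (0.01 m) cuvette; samples are
#' assumed diluted into the linear regime (ABS550 < 0.8) upstream.
#'
#' @param ABS550 Optical density at 550 nm.
#' @param DCW Biomass concentration, mg L^-1 (> 0).
#' @return Absorption coefficient, L mg^-1 m^-1.
#' @examples
#' ka_from_od(0.5, 100)   # 0.5
#' @export
ka_from_od <- function(ABS550, DCW) {
  if (any(DCW <= 0)) stop("DCW must be strictly positive")
  if (any(ABS550 < 0)) stop("ABS550 must be non-negative")
  ABS550 / (0.01 * DCW)
}

#' Replicated observation set for calibration
#'
#' Long-format container for replicated measurements of the state
#' variables on sampling days.
#'
#' @param data Data frame with columns `day`, `replicate`, `variable`
#'   (one of `"X"`, `"N"`, `"Q"`) and `value`.
#' @param nitrogen_N0 Initial medium nitrogen of the experiment,
#'   mg N L^-1 (metadata).
#' @param reactor_id Free-text reactor identifier (metadata).
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(data, nitrogen_N0 = NA_real_, reactor_id = "") {
  stopifnot(is.data.frame(data),
            all(c("day", "replicate", "variable", "value") %in% names(data)))
  if (!all(data$variable %in% c("X", "N", "Q")))
    stop("variable must be one of 'X', 'N', 'Q'")
  if (any(data$value < 0)) stop("negative measurements are not allowed")
  structure(list(data = data,
                 days = sort(unique(data$day)),
                 variables = intersect(c("X", "N", "Q"),
                                       unique(data$variable)),
                 m = max(table(data$day, data$variable)),
                 nitrogen_N0 = nitrogen_N0,
                 reactor_id = reactor_id),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("observation_set: %d records, variables {%s}, %d days, <= %d replicates\n",
              nrow(x$data), paste(x$variables, collapse = ", "),
              length(x$days), x$m))
  invisible(x)
}

#' Read / write the observation-set CSV dialect
#'
#' Comma-separated, dot decimal, mandatory header
#' `day,replicate,variable,value`.
#'
#' @param file Path.
#' @param nitrogen_N0,reactor_id Metadata passed to [observation_set()].
#' @return An `observation_set` (read) or `file` invisibly (write).
#' @export
read_observations <- function(file, nitrogen_N0 = NA_real_, reactor_id = "") {
  observation_set(read.csv(file), nitrogen_N0 = nitrogen_N0,
                  reactor_id = reactor_id)
}

#' @rdname read_observations
#' @param obs An `observation_set`.
#' @export
write_observations <- function(obs, file) {
  write.csv(obs$data, file, row.names = FALSE)
  invisible(file)
}

#' Weighted normalized root-mean-square error
#'
#' The calibration objective:
#' `NRMSE = sqrt( 1/(p q m) * sum_k sum_j sum_i w_{k,j} (pred - obs)^2 )`
#' over variables `k`, sampling days `j` and replicates `i`. Weights
#' emphasize the late growth phase, where harvest decisions are made:
#' biomass residuals are weighted by the day-mean biomass (late, large
#' values count more), quota residuals by the reciprocal day-mean quota
#' (late, small quotas count more) and medium-nitrogen residuals are
#' unweighted. Day means are taken over the replicates present.
#'
#' @param obs An [observation_set()].
#' @param predicted Data frame with columns `day`, `variable`, `value`:
#'   the model trajectory sampled at every observed (day, variable).
#' @return Scalar objective value (non-negative; 0 iff a perfect fit).
#' @export
weighted_nrmse <- function(obs, predicted) {
  d <- obs$data
  key <- paste(d$day, d$variable)
  pkey <- paste(predicted$day, predicted$variable)
  gap <- setdiff(unique(key), unique(pkey))
  if (length(gap) > 0L)
    stop("missing predictions for (day, variable): ",
         paste(gap, collapse = "; "))
  pred <- predicted$value[match(key, pkey)]
  day_mean <- stats::ave(d$value, d$day, d$variable, FUN = mean)
  w <- rep(1, nrow(d))
  w[d$variable == "X"] <- day_mean[d$variable == "X"]
  w[d$variable == "Q"] <- 1 / day_mean[d$variable == "Q"]
  p_ <- length(obs$variables)
  q_ <- length(obs$days)
  m_ <- obs$m
  sqrt(sum(w * (pred - d$value)^2) / (p_ * q_ * m_))
}

# Simulate and sample the model at the observation days. A coarse output
# grid suffices: the solver is adaptive and every segment boundary (and
# hence every whole-day sampling time) is hit exactly.
predict_at_observations <- function(obs, initial, reactor, schedule, p,
                                    dt_out = 0.5, rtol = 1e-7, atol = 1e-9) {
  res <- simulate_batch(initial, reactor, schedule, p,
                        duration = max(obs$days) + 1e-6,
                        dt_out = dt_out, rtol = rtol, atol = atol)
  idx <- vapply(obs$days, function(d) which.min(abs(res$t - d)), integer(1))
  off <- max(abs(res$t[idx] - obs$days))
  if (off > 1e-6)
    stop(sprintf("dense output misses an observation day by %g days", off))
  do.call(rbind, lapply(obs$variables, function(v)
    data.frame(day = obs$days, variable = v,
               value = res[[v]][idx])))
}

# Internal log-scale transform enforcing positivity, Q_min < Q_max and
# n > 1 by construction. The "Q_max" component carries log(Q_max - Q_min)
# and "n" carries log(n - 1):
#   theta = (log mu_max, log K_d, log Q_min, log(Q_max - Q_min),
#            log U_max, log K_N, log K_I, log(n - 1))
params_to_theta <- function(p, free = kinetic_parameter_names()) {
  full <- c(mu_max = log(p$mu_max), K_d = log(p$K_d),
            Q_min = log(p$Q_min), Q_max = log(p$Q_max - p$Q_min),
            U_max = log(p$U_max), K_N = log(p$K_N),
            K_I = log(p$K_I), n = log(p$n - 1))
  full[free]
}

theta_to_params <- function(theta, template, free) {
  full <- params_to_theta(template)
  full[free] <- theta
  q_min <- exp(full[["Q_min"]])
  modifyList(template,
             list(mu_max = exp(full[["mu_max"]]), K_d = exp(full[["K_d"]]),
                  Q_min = q_min, Q_max = q_min + exp(full[["Q_max"]]),
                  U_max = exp(full[["U_max"]]), K_N = exp(full[["K_N"]]),
                  K_I = exp(full[["K_I"]]), n = 1 + exp(full[["n"]])))
}

#' Fit the kinetic parameters to an observation set
#'
#' Derivative-free Nelder-Mead simplex minimization of the weighted NRMSE
#' objective ([weighted_nrmse()]) over the eight kinetic constants; the
#' composition-correlation coefficients are held fixed (refit them with
#' [fit_empirical_correlations()]). Parameters are log-transformed
#' internally so positivity, `Q_min < Q_max` and `n > 1` hold by
#' construction. The simplex stops after `max_iter` outer iterations
#' (default 50; an outer iteration is roughly two objective evaluations
#' once the initial simplex is built) or earlier when the relative
#' improvement of the objective falls below `rel_tol`; every evaluation
#' is logged so the best-so-far NRMSE trajectory can be reported per
#' iteration.
#'
#' @param obs An [observation_set()] covering at least two state
#'   variables and two sampling days.
#' @param initial A [culture_state()] for the underlying batch simulation.
#' @param reactor A [reactor_config()].
#' @param schedule A [light_schedule()]; defaults to the reactor's
#'   photoperiod.
#' @param init Starting [kinetic_parameters()]; defaults to the
#'   literature-based guess.
#' @param freeze Character vector of parameter names excluded from the
#'   fit (e.g. `c("K_d", "K_N", "U_max")`, the constants the model is
#'   insensitive to).
#' @param max_iter Maximum simplex iterations.
#' @param rel_tol Relative convergence tolerance of the simplex (stop
#'   once the objective stops improving by more than this fraction).
#' @param restarts Number of simplex restarts: after convergence the
#'   simplex is rebuilt around the incumbent and re-run, a standard
#'   remedy for premature collapse in narrow valleys. 0 = single run.
#' @param sim_rtol,sim_atol Integrator tolerances used inside the
#'   objective.
#' @return A `fit_report`: list with `parameters` (fitted), `init`,
#'   `nrmse` (final), `nrmse_trajectory` (per recorded iteration),
#'   `convergence` flag, `iterations`, and per-variable RMS residuals.
#' @export
fit_parameters <- function(obs, initial, reactor, schedule = NULL,
                           init = initial_parameter_guess(),
                           freeze = character(0),
                           max_iter = 50, rel_tol = 0.01, restarts = 0,
                           sim_rtol = 1e-7, sim_atol = 1e-9) {
  if (is.null(schedule)) schedule <- light_schedule(reactor$photoperiod_light_h)
  if (length(obs$variables) < 2L)
    stop("observation set must cover at least two state variables")
  if (length(obs$days) < 2L)
    stop("observation set must cover at least two sampling days")
  init <- validate_parameters(init)
  bad <- setdiff(freeze, kinetic_parameter_names())
  if (length(bad) > 0L)
    stop("unknown parameter name(s) in freeze: ", paste(bad, collapse = ", "))
  free <- setdiff(kinetic_parameter_names(), freeze)
  eval_log <- numeric(0)
  objective <- function(theta) {
    p_try <- theta_to_params(setNames(theta, free), init, free)
    v <- tryCatch({
      init_adj <- initial
      # keep the simulated inoculum quota inside the candidate bounds
      init_adj$Q <- min(max(initial$Q, p_try$Q_min), p_try$Q_max)
      pred <- predict_at_observations(obs, init_adj, reactor, schedule,
                                      p_try, rtol = sim_rtol, atol = sim_atol)
      weighted_nrmse(obs, pred)
    }, error = function(e) NA_real_)
    if (!is.finite(v)) v <- 1e6
    eval_log <<- c(eval_log, v)
    v
  }
  theta <- params_to_theta(init, free)
  if (objective(theta) >= 1e6)
    stop("objective is non-finite at the initial parameters")
  eval_log <- eval_log[1]   # keep the probe as evaluation 1
  n_free <- length(free)
  simplex_evals <- n_free + 1L
  max_eval <- simplex_evals + 2L * max_iter
  iter_done <- 0L
  for (run in seq_len(restarts + 1L)) {
    # each restart rebuilds the simplex around the incumbent with a wider
    # initial spread (parscale doubles per restart) so a collapse into a
    # shallow local basin can be escaped; the incumbent is a vertex, so
    # the objective never worsens across restarts
    fit <- optim(theta, objective, method = "Nelder-Mead",
                 control = list(maxit = max_eval, reltol = rel_tol,
                                parscale = rep(2^(run - 1L), n_free),
                                warn.1d.NelderMead = FALSE))
    theta <- fit$par
    convergence <- fit$convergence == 0L
    iter_done <- iter_done +
      max(0L, ceiling((fit$counts[["function"]] - simplex_evals) / 2))
  }
  # best objective seen up to the end of each outer iteration
  best <- cummin(eval_log)
  iter_idx <- unique(pmin(length(best),
                          simplex_evals + 2L * seq_len(max(iter_done, 1L))))
  trace <- c(best[1], best[iter_idx])
  if (!is.finite(fit$value) || fit$value >= 1e6)
    stop("simplex failed to find a finite objective; best so far:\n",
         paste(utils::capture.output(print(
           theta_to_params(setNames(theta, free), init, free))),
           collapse = "\n"))
  fitted <- validate_parameters(
    theta_to_params(setNames(theta, free), init, free))
  init_adj <- initial
  init_adj$Q <- min(max(initial$Q, fitted$Q_min), fitted$Q_max)
  pred <- predict_at_observations(obs, init_adj, reactor, schedule, fitted,
                                  rtol = sim_rtol, atol = sim_atol)
  d <- obs$data
  pv <- pred$value[match(paste(d$day, d$variable),
                         paste(pred$day, pred$variable))]
  resid_rms <- tapply((pv - d$value)^2, d$variable,
                      function(z) sqrt(mean(z)))
  structure(list(parameters = fitted, init = init,
                 nrmse = trace[length(trace)],
                 nrmse_trajectory = trace,
                 convergence = convergence,
                 iterations = iter_done,
                 residual_rms = resid_rms),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report: NRMSE %.4g -> %.4g in %d iterations (%s)\n",
              x$nrmse_trajectory[1], x$nrmse, x$iterations,
              if (x$convergence) "converged" else "iteration limit"))
  print(x$parameters)
  invisible(x)
}

#' Data-driven initial estimates of the kinetic constants
#'
#' Implements the pre-fit heuristics: the maximum growth rate is the
#' slope of `ln(OD)` versus time over the exponential phase; the quota
#' bounds are read from measurements on a nitrogen-replete early day
#' (`Q_max`) and a depleted late day (`Q_min`). All other constants come
#' from the literature-based defaults ([initial_parameter_guess()]).
#'
#' @param od_times,od_values Optional exponential-phase OD series
#'   (>= 3 points). A non-monotone series triggers a warning.
#' @param quota_early,quota_late Optional measured quotas on the replete
#'   and depleted days.
#' @return A `kinetic_parameters` object.
#' @examples
#' estimate_initial_parameters(0:3, 2^(0:3) * 0.05)  # mu_max = ln 2
#' @export
estimate_initial_parameters <- function(od_times = NULL, od_values = NULL,
                                        quota_early = NULL,
                                        quota_late = NULL) {
  p <- initial_parameter_guess()
  if (!is.null(od_times)) {
    stopifnot(length(od_times) == length(od_values), length(od_times) >= 3)
    if (any(diff(od_values) <= 0))
      warning("OD series is not strictly increasing; slope may not reflect exponential growth")
    p$mu_max <- unname(coef(lm(log(od_values) ~ od_times))[2])
  }
  if (!is.null(quota_early)) p$Q_max <- quota_early
  if (!is.null(quota_late)) p$Q_min <- quota_late
  validate_parameters(p)
}

#' Refit the empirical composition correlations
#'
#' Linear least squares for the quota dependence of the absorption
#' coefficient (`Ka = slope * Q + intercept`) and damped least squares
#' (Levenberg-Marquardt, positivity-constrained) for the reciprocal
#' quota-TFA law (`C_TFA = a * Q^-b + c`).
#'
#' @param ka_data Optional data frame with columns `Q`, `Ka` (>= 3 rows).
#' @param tfa_data Optional data frame with columns `Q`, `TFA` (>= 3 rows).
#' @param p Parameter set to update.
#' @return `p` with the refitted coefficients.
#' @export
fit_empirical_correlations <- function(ka_data = NULL, tfa_data = NULL,
                                       p = kinetic_parameters()) {
  if (!is.null(ka_data)) {
    stopifnot(all(c("Q", "Ka") %in% names(ka_data)))
    if (nrow(ka_data) < 3 || length(unique(ka_data$Q)) < 2)
      stop("ka_data: need >= 3 pairs with distinct quotas")
    co <- coef(lm(Ka ~ Q, data = ka_data))
    p$ka_intercept <- unname(co[1])
    p$ka_slope <- unname(co[2])
  }
  if (!is.null(tfa_data)) {
    stopifnot(all(c("Q", "TFA") %in% names(tfa_data)))
    if (nrow(tfa_data) < 3)
      stop("tfa_data: the three-parameter power law needs >= 3 pairs")
    fit <- minpack.lm::nlsLM(
      TFA ~ a * Q^(-b) + cc, data = tfa_data,
      start = list(a = p$tfa_coeff, b = p$tfa_exponent, cc = p$tfa_offset),
      lower = c(a = 1e-8, b = 1e-8, cc = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- coef(fit)
    p$tfa_coeff <- unname(co["a"])
    p$tfa_exponent <- unname(co["b"])
    p$tfa_offset <- unname(co["cc"])
  }
  validate_parameters(p)
}
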