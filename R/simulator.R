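#' Daily light:dark schedule
#'
#' @param light_hours Hours of light per 24 h day.
#' @param alignment Time of day (hours) at which the light phase starts;
#'   default 0 (lights on at the start of each simulated day).
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule(12)        # 12:12 light:dark
#' light_schedule(16)        # 16:8
#' @export
light_schedule <- function(light_hours = 12, alignment = 0) {
  stopifnot(light_hours >= 0, light_hours <= 24,
            alignment >= 0, alignment < 24)
  structure(list(light_hours = light_hours, alignment = alignment),
            class = "light_schedule")
}

#' Repeated-batch harvest policy
#'
#' @param batch_days Days of batch operation before the first harvest.
#' @param interval Days between successive harvests.
#' @param fraction Volume fraction of the broth harvested and replaced by
#'   fresh medium at each event, in (0, 1).
#' @param refresh_nitrogen_N0 Nitrogen concentration of the replacement
#'   medium, mg N L^-1.
#' @param n_cycles Number of harvest cycles.
#' @return An object of class `harvest_policy`.
#' @export
harvest_policy <- function(batch_days = 8, interval = 3, fraction = 0.6,
                           refresh_nitrogen_N0, n_cycles = 4) {
  stopifnot(batch_days >= 0, interval > 0,
            fraction > 0, fraction < 1,
            refresh_nitrogen_N0 >= 0, n_cycles >= 1)
  structure(list(batch_days = batch_days, interval = interval,
                 fraction = fraction,
                 refresh_nitrogen_N0 = refresh_nitrogen_N0,
                 n_cycles = n_cycles),
            class = "harvest_policy")
}

#' State derivatives of the Droop-Monod model
#'
#' Right-hand side of the three state equations:
#' `dX/dt = mu X - K_d X`, `dQ/dt = U - mu Q`, `dN/dt = -U X`, with the
#' average light intensity and absorption coefficient recomputed from the
#' current `(X, Q)` at every evaluation. Growth stops instantaneously in
#' the dark (`mu = 0`); decay and nitrogen uptake continue by default
#' (decay is a biomass property and the Droop formulation decouples
#' uptake from growth), controlled by `dark_decay` / `dark_uptake`.
#'
#' @param s A [culture_state()] (or list with `X`, `N`, `Q`).
#' @param light_on Logical; is the light phase active?
#' @param reactor A [reactor_config()].
#' @param p A [kinetic_parameters()].
#' @param dark_decay,dark_uptake Keep decay / uptake active in the dark.
#' @param iav_fun Optional pre-built average-intensity function from
#'   [make_iav_function()]; built on the fly when omitted.
#' @return Named numeric vector `c(dX, dQ, dN)`, day^-1 units.
#' @export
derivatives <- function(s, light_on, reactor, p,
                        dark_decay = TRUE, dark_uptake = TRUE,
                        iav_fun = NULL) {
  if (is.null(iav_fun)) iav_fun <- make_iav_function(reactor)
  X <- s$X; N <- s$N; Q <- s$Q
  if (!all(is.finite(c(X, N, Q))) || X < 0 || N < 0)
    stop("invalid state: X, N, Q must be finite with X >= 0, N >= 0")
  rhs_core(c(X, Q, N), light_on, p, iav_fun, dark_decay, dark_uptake)
}

# Core RHS on the raw state vector y = (X, Q, N); tolerant of the tiny
# negative N excursions an adaptive integrator can produce.
rhs_core <- function(y, light_on, p, iav_fun, dark_decay, dark_uptake) {
  X <- max(y[1], 0)
  Q <- clamp_quota(y[2], p, strict_min = FALSE)
  N <- max(y[3], 0)
  mu <- 0
  if (light_on) {
    Ka <- absorption_coefficient(Q, p)
    mu <- growth_rate(iav_fun(Ka, X), Q, p)
  }
  U <- if (light_on || dark_uptake) uptake_rate(N, Q, p) else 0
  Kd <- if (light_on || dark_decay) p$K_d else 0
  c(dX = mu * X - Kd * X, dQ = U - mu * Q, dN = -U * X)
}

# Scalar fast path for the integrator: constants unpacked once, no
# vectorized dispatch inside the solver loop. Semantics identical to
# rhs_core (a test asserts this).
make_rhs <- function(p, iav_fun, dark_decay, dark_uptake) {
  mu_max <- p$mu_max; K_d <- p$K_d; Q_min <- p$Q_min; Q_max <- p$Q_max
  U_max <- p$U_max; K_N <- p$K_N; n <- p$n; KIn <- p$K_I^p$n
  ka_s <- p$ka_slope; ka_i <- p$ka_intercept
  droop_norm <- 1 - Q_min / Q_max
  function(t, y, parms, light) {
    X <- y[1]; Q <- y[2]; N <- y[3]
    if (X < 0) X <- 0
    if (N < 0) N <- 0
    if (Q < Q_min) Q <- Q_min else if (Q > Q_max) Q <- Q_max
    mu <- 0
    if (light) {
      Iav <- iav_fun(ka_s * Q + ka_i, X)
      if (Iav > 0) {
        In <- Iav^n
        mu <- mu_max * In / (KIn + In) * (1 - Q_min / Q) / droop_norm
      }
    }
    U <- if (light || dark_uptake) U_max * N / (K_N + N) * (1 - Q / Q_max)
         else 0
    Kd <- if (light || dark_decay) K_d else 0
    list(c(mu * X - Kd * X, U - mu * Q, -U * X))
  }
}

# Light/dark switch times covering [t0, t1] for a daily schedule.
phase_breaks <- function(schedule, t0, t1) {
  h <- schedule$light_hours / 24
  al <- schedule$alignment / 24
  days <- seq(floor(t0) - 1, ceiling(t1) + 1)
  br <- sort(unique(c(days + al, if (h > 0 && h < 1) days + al + h)))
  br <- br[br > t0 + 1e-12 & br < t1 - 1e-12]
  c(t0, br, t1)
}

is_light_phase <- function(t, schedule) {
  h <- schedule$light_hours / 24
  tod <- (t - schedule$alignment / 24) %% 1
  tod < h - 1e-12 | h >= 1 - 1e-12
}

# Integrate [t0, t1] across light/dark switches, restarting the solver at
# each discontinuity. Returns the dense output matrix (t, X, Q, N).
integrate_span <- function(y, t0, t1, schedule, p, iav_fun,
                           dark_decay, dark_uptake, dt_out, rtol, atol,
                           ode_rhs = make_rhs(p, iav_fun, dark_decay,
                                              dark_uptake)) {
  br <- phase_breaks(schedule, t0, t1)
  out <- NULL
  for (i in seq_len(length(br) - 1L)) {
    a <- br[i]; b <- br[i + 1L]
    light <- is_light_phase((a + b) / 2, schedule)
    tt <- unique(c(seq(a, b, by = dt_out), b))
    seg <- deSolve::ode(y, tt, ode_rhs, NULL, light = light,
                        rtol = rtol, atol = atol)
    if (any(!is.finite(seg[, -1])))
      stop("integration produced non-finite state; trajectory:\n",
           paste(utils::capture.output(print(utils::tail(seg))), collapse = "\n"))
    y <- seg[nrow(seg), 2:4]
    out <- rbind(out, if (is.null(out)) seg else seg[-1, , drop = FALSE])
  }
  out
}

# First time N falls below `threshold`, refined to ~1e-3 day by
# re-integrating the bracketing output interval on a fine grid.
find_depletion <- function(traj, schedule, p, iav_fun,
                           dark_decay, dark_uptake, rtol, atol,
                           threshold) {
  below <- which(traj[, "N"] < threshold)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(traj[1L, 1L])
  t_lo <- traj[i - 1L, 1L]; t_hi <- traj[i, 1L]
  y <- traj[i - 1L, 2:4]
  fine <- integrate_span(y, t_lo, t_hi, schedule, p, iav_fun,
                         dark_decay, dark_uptake,
                         dt_out = max((t_hi - t_lo) / 50, 1e-4),
                         rtol, atol)
  j <- which(fine[, "N"] < threshold)[1L]
  if (is.na(j)) t_hi else fine[j, 1L]
}

# Decorate a raw (t, X, Q, N) trajectory with derived optical and
# composition series and wrap as a simulation_result.
as_simulation_result <- function(traj, reactor, schedule, p, iav_fun,
                                 harvests, depletion_time) {
  X <- pmax(traj[, "X"], 0)
  Q <- clamp_quota(traj[, "Q"], p, strict_min = FALSE)
  N <- pmax(traj[, "N"], 0)
  Ka <- absorption_coefficient(Q, p)
  Iav <- vapply(seq_along(X), function(i) iav_fun(Ka[i], X[i]), numeric(1))
  comp <- composition(Q, X, p)
  res <- data.frame(t = traj[, 1L], X = X, N = N, Q = Q,
                    Iav = Iav, Ka = Ka,
                    C_TFA = comp$C_TFA, C_EPA = comp$C_EPA,
                    epa_fraction = comp$epa_fraction,
                    TFA_mg_L = comp$TFA_volumetric,
                    EPA_mg_L = comp$EPA_volumetric)
  structure(res,
            class = c("simulation_result", "data.frame"),
            reactor = reactor, schedule = schedule, parameters = p,
            harvests = harvests, depletion_time = depletion_time)
}

#' Simulate a batch culture
#'
#' Integrates the three-state Droop-Monod model under a daily light:dark
#' schedule. Integration proceeds in sub-intervals ending exactly at each
#' light/dark switch, with the adaptive solver restarted across the
#' discontinuity. The first time the medium nitrogen falls below
#' `depletion_threshold` is located to about 1e-3 day and stored as the
#' `depletion_time` attribute; a nitrogen-balance diagnostic
#' (relative drift of `N + Q X` corrected for decay losses) is stored as
#' `conservation_residual`.
#'
#' @param initial A [culture_state()] giving `X`, `N`, `Q` at `t = 0`.
#' @param reactor A [reactor_config()].
#' @param schedule A [light_schedule()]; defaults to the reactor's
#'   photoperiod.
#' @param p A [kinetic_parameters()].
#' @param duration Length of the simulation, days.
#' @param dt_out Output grid spacing, days.
#' @param rtol,atol Integrator tolerances.
#' @param dark_decay,dark_uptake See [derivatives()].
#' @param depletion_threshold Nitrogen concentration (mg N L^-1) below
#'   which the medium is considered exhausted.
#' @return A `simulation_result`: a data frame with one row per output
#'   time and columns `t`, `X`, `N`, `Q`, `Iav`, `Ka`, `C_TFA`, `C_EPA`,
#'   `epa_fraction`, `TFA_mg_L`, `EPA_mg_L`, plus attributes `harvests`,
#'   `depletion_time`, `conservation_residual`.
#' @examples
#' sc <- scenario("5L_flat_panel_4xf2")
#' res <- simulate_batch(sc$initial, sc$reactor, sc$schedule,
#'                       kinetic_parameters(), duration = 16)
#' attr(res, "depletion_time")
#' @export
simulate_batch <- function(initial, reactor, schedule = NULL,
                           p = kinetic_parameters(), duration,
                           dt_out = 0.02, rtol = 1e-8, atol = 1e-10,
                           dark_decay = TRUE, dark_uptake = TRUE,
                           depletion_threshold = 0.01) {
  if (is.null(schedule)) schedule <- light_schedule(reactor$photoperiod_light_h)
  stopifnot(duration > 0)
  if (initial$Q < p$Q_min - .Q_TOL || initial$Q > p$Q_max + .Q_TOL)
    stop(sprintf("initial quota %g outside [Q_min, Q_max] = [%g, %g]",
                 initial$Q, p$Q_min, p$Q_max))
  iav_fun <- make_iav_function(reactor)
  y0 <- c(X = initial$X, Q = initial$Q, N = initial$N)
  traj <- integrate_span(y0, 0, duration, schedule, p, iav_fun,
                         dark_decay, dark_uptake, dt_out, rtol, atol)
  tdep <- find_depletion(traj, schedule, p, iav_fun, dark_decay,
                         dark_uptake, rtol, atol, depletion_threshold)
  res <- as_simulation_result(traj, reactor, schedule, p, iav_fun,
                              harvests = data.frame(time = numeric(0),
                                                    fraction = numeric(0),
                                                    biomass_removed = numeric(0)),
                              depletion_time = tdep)
  # nitrogen balance: d/dt (N + QX) = -Kd QX (when decay is active)
  B <- res$N + res$Q * res$X
  qx <- res$Q * res$X
  dt <- diff(res$t)
  kd_eff <- if (dark_decay) p$K_d else
    p$K_d * is_light_phase(res$t[-1] - 1e-9, schedule)
  decay_loss <- sum(kd_eff * (qx[-1] + qx[-length(qx)]) / 2 * dt)
  attr(res, "conservation_residual") <-
    (B[length(B)] - B[1] + decay_loss) / B[1]
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %d time points over %g days\n",
              nrow(x), max(x$t)))
  cat(sprintf("  final X = %.1f mg/L, N = %.3f mg N/L, Q = %.4f\n",
              x$X[nrow(x)], x$N[nrow(x)], x$Q[nrow(x)]))
  td <- attr(x, "depletion_time")
  if (!is.na(td)) cat(sprintf("  medium nitrogen exhausted at t = %.3f d\n", td))
  h <- attr(x, "harvests")
  if (nrow(h) > 0)
    cat(sprintf("  %d harvests, %.0f mg/L biomass removed in total\n",
                nrow(h), sum(h$biomass_removed)))
  invisible(x)
}

#' Simulate a repeated-batch culture
#'
#' Runs `policy$batch_days` of batch operation, then `policy$n_cycles`
#' harvest cycles. At each harvest a fraction `f` of the broth is removed
#' and replaced by fresh medium: `X <- (1-f) X`,
#' `N <- (1-f) N + f N_fresh`; the intracellular quota `Q` is unchanged.
#' The biomass removed per litre (`f X`) is accumulated in the harvest
#' ledger.
#'
#' @inheritParams simulate_batch
#' @param policy A [harvest_policy()].
#' @return A `simulation_result` (see [simulate_batch()]) whose
#'   `harvests` attribute records each event.
#' @export
simulate_repeated_batch <- function(initial, reactor, schedule = NULL,
                                    p = kinetic_parameters(), policy,
                                    dt_out = 0.02, rtol = 1e-8, atol = 1e-10,
                                    dark_decay = TRUE, dark_uptake = TRUE,
                                    depletion_threshold = 0.01) {
  if (is.null(schedule)) schedule <- light_schedule(reactor$photoperiod_light_h)
  stopifnot(inherits(policy, "harvest_policy"))
  if (initial$Q < p$Q_min - .Q_TOL || initial$Q > p$Q_max + .Q_TOL)
    stop(sprintf("initial quota %g outside [Q_min, Q_max] = [%g, %g]",
                 initial$Q, p$Q_min, p$Q_max))
  iav_fun <- make_iav_function(reactor)
  y <- c(X = initial$X, Q = initial$Q, N = initial$N)
  spans <- c(policy$batch_days, rep(policy$interval, policy$n_cycles))
  t <- 0
  traj <- NULL
  harvests <- data.frame(time = numeric(0), fraction = numeric(0),
                         biomass_removed = numeric(0))
  for (k in seq_along(spans)) {
    if (spans[k] > 0) {
      seg <- integrate_span(y, t, t + spans[k], schedule, p, iav_fun,
                            dark_decay, dark_uptake, dt_out, rtol, atol)
      y <- seg[nrow(seg), 2:4]
      traj <- rbind(traj, if (is.null(traj)) seg else seg[-1, , drop = FALSE])
      t <- t + spans[k]
    }
    if (k <= policy$n_cycles) {   # harvest after every span except none
      f <- policy$fraction
      removed <- f * y[1]
      harvests <- rbind(harvests,
                        data.frame(time = t, fraction = f,
                                   biomass_removed = removed))
      y[1] <- (1 - f) * y[1]
      y[3] <- (1 - f) * y[3] + f * policy$refresh_nitrogen_N0
      traj <- rbind(traj, c(t, y))  # post-harvest state at the same t
    }
  }
  tdep <- find_depletion(traj, schedule, p, iav_fun, dark_decay,
                         dark_uptake, rtol, atol, depletion_threshold)
  as_simulation_result(traj, reactor, schedule, p, iav_fun,
                       harvests = harvests, depletion_time = tdep)
}

#' Biomass productivity of a simulated culture
#'
#' Two definitions:
#' * `"instantaneous_batch"`: `DCW(t) / t`, the batch productivity at each
#'   output time (undefined at `t = 0`, which is excluded).
#' * `"overall"`: cumulative harvested biomass plus standing-biomass gain
#'   per litre divided by elapsed time,
#'   `(sum harvested + X(t) - X(0)) / t` — the repeated-batch measure over
#'   the whole run.
#'
#' @param result A `simulation_result`.
#' @param mode Productivity definition.
#' @return Data frame with columns `t` (days) and `productivity`
#'   (mg L^-1 day^-1).
#' @export
biomass_productivity <- function(result,
                                 mode = c("instantaneous_batch", "overall")) {
  mode <- match.arg(mode)
  stopifnot(nrow(result) > 0)
  keep <- result$t > 0
  t <- result$t[keep]
  if (mode == "instantaneous_batch") {
    prod <- result$X[keep] / t
  } else {
    h <- attr(result, "harvests")
    cum_harv <- vapply(t, function(ti)
      sum(h$biomass_removed[h$time <= ti + 1e-9]), numeric(1))
    prod <- (cum_harv + result$X[keep] - result$X[1]) / t
  }
  data.frame(t = t, productivity = prod)
}

#' Day of maximum batch productivity on a daily grid
#'
#' Evaluates `DCW(t)/t` at integer days and returns the argmax day.
#'
#' @param result A `simulation_result`.
#' @return Integer day.
#' @export
peak_productivity_day <- function(result) {
  days <- seq_len(floor(max(result$t)))
  prod <- vapply(days, function(d)
    result$X[which.min(abs(result$t - d))] / d, numeric(1))
  days[which.max(prod)]
}

#' Initial biomass concentration from optical density
#'
#' Inverts the absorbance measurement model `ABS550 = 0.01 * Ka * DCW`
#' (1 cm cuvette) to estimate the inoculum biomass from an optical
#' density reading, using the quota-dependent absorption coefficient at
#' the inoculum quota (nutrient-replete inocula carry `Q = Q_max`).
#'
#' @param OD550 Optical density at 550 nm.
#' @param p A [kinetic_parameters()].
#' @param Q0 Inoculum quota; defaults to `Q_max`.
#' @return Biomass concentration, mg L^-1.
#' @examples
#' biomass_from_od(0.05)   # ~9.3 mg/L
#' @export
biomass_from_od <- function(OD550, p = kinetic_parameters(), Q0 = p$Q_max) {
  stopifnot(OD550 >= 0)
  OD550 / (0.01 * absorption_coefficient(Q0, p))
}

#' Write a simulation result (and harvest ledger) as CSV
#'
#' @param result A `simulation_result`.
#' @param file Path of the main time-series CSV.
#' @param harvest_file Optional path for the harvest-event CSV.
#' @return `file`, invisibly.
#' @export
write_simulation_csv <- function(result, file, harvest_file = NULL) {
  df <- as.data.frame(result)
  names(df) <- c("t_days", "X_mg_L", "N_mgN_L", "Q_mgN_mgDCW", "Iav", "Ka",
                 "C_TFA", "C_EPA", "epa_fraction", "TFA_mg_L", "EPA_mg_L")
  write.csv(df, file, row.names = FALSE)
  if (!is.null(harvest_file))
    write.csv(attr(result, "harvests"), harvest_file, row.names = FALSE)
  invisible(file)
}
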