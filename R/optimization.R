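#' Grid search over repeated-batch harvest strategies
#'
#' Runs [simulate_repeated_batch()] for every combination of harvest
#' interval and harvest fraction and reports the overall biomass
#' productivity (harvested plus standing biomass gain per litre per day)
#' of each cell, the best cell(s), and the equal-duration pure-batch
#' baseline for the optimum. Cells are independent; a failing cell is
#' recorded as `NA` with its error message rather than aborting the grid.
#'
#' @param initial A [culture_state()].
#' @param reactor A [reactor_config()].
#' @param schedule A [light_schedule()]; defaults to the reactor's
#'   photoperiod.
#' @param p A [kinetic_parameters()].
#' @param batch_days Days of batch operation before the first harvest.
#' @param intervals Harvest intervals to scan, days.
#' @param fractions Harvest fractions to scan, in (0, 1).
#' @param n_cycles Harvest cycles per strategy.
#' @param refresh_nitrogen_N0 Nitrogen concentration of the replacement
#'   medium, mg N L^-1.
#' @param dt_out,rtol,atol Passed to the simulator.
#' @return A `harvest_grid_result`: list with `grid` (long data frame:
#'   `interval`, `fraction`, `total_days`, `productivity`, `error`),
#'   `best` (the argmax row(s), ties included), `batch_productivity`
#'   (equal-duration batch `DCW(T)/T` at the optimum duration) and
#'   `improvement_pct`.
#' @export
harvest_grid_search <- function(initial, reactor, schedule = NULL,
                                p = kinetic_parameters(),
                                batch_days = 8,
                                intervals = 1:7,
                                fractions = seq(0.1, 0.9, by = 0.1),
                                n_cycles = 4,
                                refresh_nitrogen_N0,
                                dt_out = 0.1, rtol = 1e-8, atol = 1e-10) {
  if (is.null(schedule)) schedule <- light_schedule(reactor$photoperiod_light_h)
  cells <- expand.grid(interval = intervals, fraction = fractions)
  cells$total_days <- batch_days + n_cycles * cells$interval
  cells$productivity <- NA_real_
  cells$error <- ""
  for (i in seq_len(nrow(cells))) {
    pol <- harvest_policy(batch_days, cells$interval[i], cells$fraction[i],
                          refresh_nitrogen_N0, n_cycles)
    out <- tryCatch({
      res <- simulate_repeated_batch(initial, reactor, schedule, p, pol,
                                     dt_out = dt_out, rtol = rtol, atol = atol)
      pr <- biomass_productivity(res, "overall")
      pr$productivity[nrow(pr)]
    }, error = function(e) e)
    if (inherits(out, "error")) cells$error[i] <- conditionMessage(out)
    else cells$productivity[i] <- out
  }
  if (all(is.na(cells$productivity)))
    stop("every grid cell failed; first error: ", cells$error[1])
  best_val <- max(cells$productivity, na.rm = TRUE)
  best <- cells[!is.na(cells$productivity) &
                  cells$productivity >= best_val * (1 - 1e-12), , drop = FALSE]
  T_best <- best$total_days[1]
  batch <- simulate_batch(initial, reactor, schedule, p, duration = T_best,
                          dt_out = dt_out, rtol = rtol, atol = atol)
  batch_prod <- batch$X[nrow(batch)] / T_best
  structure(list(grid = cells, best = best,
                 batch_productivity = batch_prod,
                 improvement_pct = 100 * (best_val / batch_prod - 1)),
            class = "harvest_grid_result")
}

#' @export
print.harvest_grid_result <- function(x, ...) {
  b <- x$best[1, ]
  cat(sprintf(paste0("harvest grid: optimum %.1f mg/L/day at fraction %.0f%%",
                     ", interval %g d (%g d total)\n"),
              b$productivity, 100 * b$fraction, b$interval, b$total_days))
  cat(sprintf("  equal-duration batch: %.1f mg/L/day (improvement %.0f%%)\n",
              x$batch_productivity, x$improvement_pct))
  invisible(x)
}

#' Overall productivity as a function of the number of harvest cycles
#'
#' Re-runs a fixed harvest strategy with 1..`max_cycles` cycles; useful to
#' show that gains beyond about five cycles are marginal.
#'
#' @inheritParams harvest_grid_search
#' @param interval,fraction The fixed strategy.
#' @param max_cycles Largest cycle count examined.
#' @return Data frame with columns `n_cycles`, `total_days`,
#'   `productivity`.
#' @export
productivity_vs_cycles <- function(initial, reactor, schedule = NULL,
                                   p = kinetic_parameters(),
                                   batch_days = 8, interval = 3,
                                   fraction = 0.6, refresh_nitrogen_N0,
                                   max_cycles = 8,
                                   dt_out = 0.1, rtol = 1e-8, atol = 1e-10) {
  if (is.null(schedule)) schedule <- light_schedule(reactor$photoperiod_light_h)
  out <- lapply(seq_len(max_cycles), function(nc) {
    pol <- harvest_policy(batch_days, interval, fraction,
                          refresh_nitrogen_N0, nc)
    res <- simulate_repeated_batch(initial, reactor, schedule, p, pol,
                                   dt_out = dt_out, rtol = rtol, atol = atol)
    pr <- biomass_productivity(res, "overall")
    data.frame(n_cycles = nc, total_days = batch_days + nc * interval,
               productivity = pr$productivity[nrow(pr)])
  })
  do.call(rbind, out)
}

#' One-at-a-time parameter sensitivity analysis
#'
#' Perturbs each kinetic constant by `+/- perturbation` (default 20%)
#' while holding the others fixed, re-simulates each scenario, and
#' reports the relative change of the final biomass and final quota.
#'
#' @param scenarios Named list of scenarios; each element is a list with
#'   fields `initial` ([culture_state()]), `reactor`, `schedule`
#'   (optional) and `duration`. See [scenario()] for packaged ones.
#' @param p Baseline [kinetic_parameters()].
#' @param parameters Constants to perturb (default: all eight).
#' @param perturbation Relative perturbation (0.2 = +/-20%).
#' @param dt_out,rtol,atol Passed to the simulator.
#' @return A `sensitivity_report`: data frame with columns `scenario`,
#'   `parameter`, `direction` (+1/-1), `final_X_change_pct`,
#'   `final_Q_change_pct`.
#' @export
sensitivity_one_at_a_time <- function(scenarios, p = kinetic_parameters(),
                                      parameters = kinetic_parameter_names(),
                                      perturbation = 0.2,
                                      dt_out = 0.05, rtol = 1e-8,
                                      atol = 1e-10) {
  stopifnot(perturbation >= 0, perturbation < 1)
  run_final <- function(sc, p_use) {
    # a perturbed Q_max below the inoculum quota (or Q_min above it)
    # moves the feasible initial quota with the bounds
    ini <- sc$initial
    ini$Q <- min(max(ini$Q, p_use$Q_min), p_use$Q_max)
    res <- simulate_batch(ini, sc$reactor, sc$schedule, p_use,
                          duration = sc$duration, dt_out = dt_out,
                          rtol = rtol, atol = atol)
    c(X = res$X[nrow(res)], Q = res$Q[nrow(res)])
  }
  rows <- list()
  for (sname in names(scenarios)) {
    sc <- scenarios[[sname]]
    base <- run_final(sc, p)
    for (par in parameters) for (dir in c(1, -1)) {
      p_pert <- p
      p_pert[[par]] <- p[[par]] * (1 + dir * perturbation)
      p_pert <- tryCatch(validate_parameters(p_pert), error = function(e) NULL)
      if (is.null(p_pert)) next   # e.g. n below 1: perturbation infeasible
      fin <- run_final(sc, p_pert)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sname, parameter = par, direction = dir,
        final_X_change_pct = 100 * (fin["X"] / base["X"] - 1),
        final_Q_change_pct = 100 * (fin["Q"] / base["Q"] - 1),
        row.names = NULL)
    }
  }
  structure(do.call(rbind, rows), class = c("sensitivity_report",
                                            "data.frame"))
}

#' @export
print.sensitivity_report <- function(x, ...) {
  df <- as.data.frame(x)
  agg <- stats::aggregate(abs(df$final_X_change_pct),
                          by = list(scenario = df$scenario,
                                    parameter = df$parameter), FUN = max)
  names(agg)[3] <- "max_abs_X_change_pct"
  agg <- agg[order(agg$scenario, -agg$max_abs_X_change_pct), ]
  cat("sensitivity (max |final biomass change| per parameter):\n")
  print(agg, row.names = FALSE)
  invisible(x)
}
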