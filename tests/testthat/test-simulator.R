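test_that("derivatives reproduce hand-evaluated rates", {
  p <- ref_params
  reactor <- ref_scenario$reactor
  # dark phase, depleted medium: only first-order decay remains
  d <- derivatives(list(X = 500, N = 0, Q = 0.05), light_on = FALSE,
                   reactor, p)
  expect_equal(unname(d), c(-p$K_d * 500, 0, 0))
  # light phase at full quota: uptake is off, growth from the averaged field
  X <- 100; N <- 40; Q <- 0.12
  Ka <- 2.74 * Q + 0.21
  a <- Ka * X * 0.05
  Iav <- 350 * (1 - exp(-a)) / a
  mu <- 2.4 * Iav^1.9 / (50^1.9 + Iav^1.9)   # Droop factor = 1 at Q_max
  d2 <- derivatives(list(X = X, N = N, Q = Q), light_on = TRUE, reactor, p)
  expect_equal(unname(d2), c(mu * X - 0.01 * X, 0 - mu * Q, 0),
               tolerance = 1e-10)
  # no growth, no decay: biomass is frozen
  p0 <- kinetic_parameters(K_d = 1e-12)
  d3 <- derivatives(list(X = 200, N = 0, Q = 0.05), light_on = FALSE,
                    reactor, p0, dark_decay = FALSE)
  expect_equal(unname(d3)[1], 0)
  expect_error(derivatives(list(X = NaN, N = 1, Q = 0.05), TRUE, reactor, p),
               "invalid state")
})

test_that("the fast integrator right-hand side matches the reference one", {
  p <- ref_params
  iav <- make_iav_function(ref_scenario$reactor)
  fast <- phaeosim:::make_rhs(p, iav, dark_decay = TRUE, dark_uptake = TRUE)
  set.seed(301)
  for (i in 1:25) {
    y <- c(runif(1, 0, 2000), runif(1, p$Q_min, p$Q_max), runif(1, 0, 60))
    light <- i %% 2 == 0
    expect_equal(fast(0, y, NULL, light)[[1]],
                 unname(phaeosim:::rhs_core(y, light, p, iav, TRUE, TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("unlimited growth is exponential at mu_max gated by the photoperiod", {
  # saturating light, vast nitrogen, decay off, uptake fast enough to hold
  # the quota at Q_max: X(t) = X0 exp(mu_max * light_fraction * t)
  p <- kinetic_parameters(K_d = 1e-9, U_max = 500, K_N = 1e-4)
  reactor <- reactor_config("flat_panel", incident_intensity_Io = 1e8,
                            path_length_L = 1e-6)
  ini <- culture_state(X = 1, N = 1e5, Q = p$Q_max)
  res <- simulate_batch(ini, reactor, light_schedule(12), p, duration = 2)
  expect_equal(res$X[nrow(res)], exp(p$mu_max * 1), tolerance = 1e-2)
})

test_that("nitrogen mass N + QX is conserved without decay", {
  p <- kinetic_parameters(K_d = 1e-12)
  res <- quick_sim(p)
  B <- res$N + res$Q * res$X
  expect_lt(max(abs(B - B[1])) / B[1], 1e-6)
  # with decay on, the balance only ever decreases
  res2 <- quick_sim()
  B2 <- res2$N + res2$Q * res2$X
  expect_true(all(diff(B2) < 1e-8))
  expect_lt(abs(attr(res2, "conservation_residual")), 1e-6)
})

test_that("the quota stays inside the Droop bounds for random conditions", {
  set.seed(302)
  p <- ref_params
  for (i in 1:5) {
    ini <- culture_state(X = runif(1, 5, 50), N = runif(1, 10, 200),
                         Q = runif(1, p$Q_min, p$Q_max))
    res <- simulate_batch(ini, ref_scenario$reactor, light_schedule(12), p,
                          duration = 10, dt_out = 0.1)
    expect_true(all(res$Q >= p$Q_min - 1e-9 & res$Q <= p$Q_max + 1e-9))
    expect_true(all(res$N >= 0))
    expect_true(all(res$X >= 0))
  }
})

test_that("the trajectory is insensitive to halving the solver tolerance", {
  res1 <- quick_sim(rtol = 1e-8, atol = 1e-10)
  res2 <- quick_sim(rtol = 5e-9, atol = 5e-11)
  X16_1 <- res1$X[nrow(res1)]
  X16_2 <- res2$X[nrow(res2)]
  expect_lt(abs(X16_1 - X16_2) / X16_2, 1e-3)
})

test_that("nitrogen depletion is detected and timed", {
  res <- quick_sim()
  td <- attr(res, "depletion_time")
  expect_false(is.na(td))
  # the recorded time brackets the threshold crossing on the dense grid
  before <- res$N[max(which(res$t < td))]
  after <- res$N[min(which(res$t > td))]
  expect_gt(before, 0.01)
  expect_lt(after, 0.01 + 1e-6)
  # a nitrogen-rich run never depletes
  rich <- scenario("5L_flat_panel_4xf2")
  rich$initial$N <- 1000
  res2 <- simulate_batch(rich$initial, rich$reactor, rich$schedule,
                         ref_params, duration = 6)
  expect_true(is.na(attr(res2, "depletion_time")))
})

test_that("harvests apply the dilution mixing rule exactly", {
  pol <- harvest_policy(batch_days = 8, interval = 3, fraction = 0.6,
                        refresh_nitrogen_N0 = 61.6, n_cycles = 2)
  res <- simulate_repeated_batch(ref_scenario$initial, ref_scenario$reactor,
                                 ref_scenario$schedule, ref_params, pol)
  h <- attr(res, "harvests")
  expect_equal(nrow(h), 2L)
  expect_equal(h$time, c(8, 11))
  i_pre <- max(which(res$t == 8)) - 1L  # row before the harvest event row
  i_post <- max(which(res$t == 8))
  expect_equal(res$X[i_post], 0.4 * res$X[i_pre], tolerance = 1e-12)
  expect_equal(res$N[i_post], 0.4 * res$N[i_pre] + 0.6 * 61.6,
               tolerance = 1e-12)
  expect_equal(res$Q[i_post], res$Q[i_pre])  # intracellular, undiluted
  expect_equal(h$biomass_removed[1], 0.6 * res$X[i_pre], tolerance = 1e-12)
})

test_that("a vanishing harvest fraction reduces to the batch trajectory", {
  pol <- harvest_policy(batch_days = 8, interval = 3, fraction = 1e-9,
                        refresh_nitrogen_N0 = 49.28, n_cycles = 2)
  rb <- simulate_repeated_batch(ref_scenario$initial, ref_scenario$reactor,
                                ref_scenario$schedule, ref_params, pol)
  batch <- quick_sim(duration = 14)
  expect_equal(rb$X[nrow(rb)], batch$X[nrow(batch)], tolerance = 1e-6)
})

test_that("productivity definitions divide gained biomass by elapsed time", {
  res <- quick_sim()
  pr <- biomass_productivity(res, "instantaneous_batch")
  expect_true(all(pr$t > 0))
  i <- which.min(abs(pr$t - 8))
  expect_equal(pr$productivity[i], res$X[which.min(abs(res$t - 8))] / pr$t[i])
  # overall mode counts harvested and standing biomass
  pol <- harvest_policy(8, 3, 0.6, refresh_nitrogen_N0 = 61.6, n_cycles = 2)
  rb <- simulate_repeated_batch(ref_scenario$initial, ref_scenario$reactor,
                                ref_scenario$schedule, ref_params, pol)
  ov <- biomass_productivity(rb, "overall")
  h <- attr(rb, "harvests")
  manual <- (sum(h$biomass_removed) + rb$X[nrow(rb)] - rb$X[1]) / 14
  expect_equal(ov$productivity[nrow(ov)], manual, tolerance = 1e-9)
})

test_that("simulation CSV export writes the documented columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  fh <- withr::local_tempfile(fileext = ".csv")
  res <- quick_sim(duration = 4)
  write_simulation_csv(res, f, fh)
  back <- read.csv(f)
  expect_named(back, c("t_days", "X_mg_L", "N_mgN_L", "Q_mgN_mgDCW", "Iav",
                       "Ka", "C_TFA", "C_EPA", "epa_fraction", "TFA_mg_L",
                       "EPA_mg_L"))
  expect_equal(nrow(back), nrow(res))
})
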