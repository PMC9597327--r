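test_that("nitrate UV absorbance converts to nitrogen concentration", {
  expect_equal(nitrate_to_nitrogen(0.3, 0.05, 1), 0.7518111,
               tolerance = 1e-6)
  expect_equal(nitrate_to_nitrogen(0.2, 0.1, 1), 0)
  expect_equal(nitrate_to_nitrogen(0.3, 0.05, 10),
               10 * nitrate_to_nitrogen(0.3, 0.05, 1))
  expect_warning(nitrate_to_nitrogen(0.1, 0.2, 1), "interference")
  expect_equal(suppressWarnings(nitrate_to_nitrogen(0.1, 0.2, 1)), 0)
})

test_that("quota follows the nitrogen depletion balance", {
  expect_equal(quota_from_depletion(49.3, 10, 400), 0.09825)
  expect_equal(quota_from_depletion(49.3, 49.3, 400), 0)
  expect_error(quota_from_depletion(49.3, 50, 400), "exceeds N0")
  expect_error(quota_from_depletion(49.3, 10, 0), "positive")
})

test_that("absorption coefficient inverts the cuvette absorbance model", {
  expect_equal(ka_from_od(0.5, 100), 0.5)
  expect_equal(ka_from_od(0, 100), 0)
  expect_equal(ka_from_od(0.5, 200), 0.25)  # inverse in biomass
  expect_error(ka_from_od(0.5, 0))
})

test_that("weighted NRMSE implements the late-phase weighting scheme", {
  # perfect fit is exactly zero
  d <- data.frame(day = rep(c(4, 8), each = 3),
                  replicate = rep(1:3, 2),
                  variable = "X",
                  value = c(100, 110, 120, 800, 810, 820))
  obs <- observation_set(d[d$replicate == 1, ])
  expect_equal(weighted_nrmse(obs, data.frame(day = c(4, 8), variable = "X",
                                              value = c(100, 800))), 0)
  # single unweighted nitrogen residual of 2 comes back unchanged
  obs1 <- observation_set(data.frame(day = 5, replicate = 1,
                                     variable = "N", value = 3))
  expect_equal(weighted_nrmse(obs1, data.frame(day = 5, variable = "N",
                                               value = 5)), 2)
  # hand-computed toy: 2 days x 2 replicates of biomass
  # day 1: obs (10, 12), pred 11, w = mean = 11 -> residuals 1, 1
  # day 2: obs (20, 22), pred 20, w = 21        -> residuals 0, 4
  # sum w r^2 = 11 + 11 + 0 + 84 = 106; /(1*2*2) = 26.5; sqrt = 5.147815
  toy <- observation_set(data.frame(day = c(1, 1, 2, 2),
                                    replicate = c(1, 2, 1, 2),
                                    variable = "X",
                                    value = c(10, 12, 20, 22)))
  pred <- data.frame(day = c(1, 2), variable = "X", value = c(11, 20))
  expect_equal(weighted_nrmse(toy, pred), sqrt(106 / 4), tolerance = 1e-12)
  # quota uses the reciprocal day-mean weight
  # obs (0.05, 0.07), pred 0.06, w = 1/0.06: sum w r^2 = 2e-4/0.06
  toyQ <- observation_set(data.frame(day = 1, replicate = 1:2,
                                     variable = "Q", value = c(0.05, 0.07)))
  predQ <- data.frame(day = 1, variable = "Q", value = 0.06)
  expect_equal(weighted_nrmse(toyQ, predQ), sqrt((2e-4 / 0.06) / 2),
               tolerance = 1e-12)
  # tripling every residual triples the objective (weights are fixed by
  # the observations, so the objective is 1-homogeneous in the residuals)
  single <- observation_set(data.frame(day = c(1, 2), replicate = 1,
                                       variable = "X", value = c(10, 20)))
  base <- weighted_nrmse(single, data.frame(day = c(1, 2), variable = "X",
                                            value = c(11, 21)))
  trip <- weighted_nrmse(single, data.frame(day = c(1, 2), variable = "X",
                                            value = c(13, 23)))
  expect_equal(trip, 3 * base, tolerance = 1e-12)
  # a missing (day, variable) prediction is reported
  expect_error(weighted_nrmse(toy, pred[1, ]), "missing predictions.*2 X")
})

test_that("initial parameter estimation uses OD slope and quota endpoints", {
  # OD doubling daily: slope of ln OD is ln 2
  est <- estimate_initial_parameters(0:3, 0.05 * 2^(0:3))
  expect_equal(est$mu_max, log(2), tolerance = 1e-12)
  # literature defaults when no data are supplied
  expect_equal(unlist(estimate_initial_parameters()[kinetic_parameter_names()]),
               c(mu_max = 2, K_d = 0.01, Q_min = 0.04, Q_max = 0.13,
                 U_max = 0.5, K_N = 0.01, K_I = 60, n = 1.9))
  # measured quota endpoints pass through
  est2 <- estimate_initial_parameters(quota_early = 0.13, quota_late = 0.04)
  expect_equal(est2$Q_max, 0.13)
  expect_equal(est2$Q_min, 0.04)
  expect_warning(estimate_initial_parameters(0:3, c(1, 2, 1.5, 3)),
                 "not strictly increasing")
  expect_error(estimate_initial_parameters(0:1, c(1, 2)))
})

test_that("empirical correlations are recovered from synthetic pairs", {
  # exact linear data reproduce the Ka correlation to rounding error
  Q <- seq(0.03, 0.15, length.out = 12)
  ka <- data.frame(Q = Q, Ka = 2.74 * Q + 0.21)
  p1 <- fit_empirical_correlations(ka_data = ka)
  expect_equal(p1$ka_slope, 2.74, tolerance = 1e-6)
  expect_equal(p1$ka_intercept, 0.21, tolerance = 1e-6)
  # noisy reciprocal power-law data recover (a, b, c) within 15%
  set.seed(501)
  tfa <- data.frame(Q = Q,
                    TFA = (3.68 * Q^(-1.32) + 42.2) * rnorm(12, 1, 0.02))
  p2 <- fit_empirical_correlations(tfa_data = tfa)
  expect_equal(p2$tfa_coeff, 3.68, tolerance = 0.15)
  expect_equal(p2$tfa_exponent, 1.32, tolerance = 0.15)
  expect_equal(p2$tfa_offset, 42.2, tolerance = 0.15)
  # underdetermined power law is refused
  expect_error(fit_empirical_correlations(
    tfa_data = data.frame(Q = c(0.05, 0.1), TFA = c(200, 100))),
    ">= 3 pairs")
})

test_that("the fit guards its inputs and converges trivially from the truth", {
  sc <- ref_scenario
  obs <- generate_observations(ref_params, sc$initial, sc$reactor,
                               sc$schedule, days = c(4, 8, 12, 16), m = 2,
                               noise = noise_model(0, 0, 0, seed = 7))
  one_var <- observation_set(obs$data[obs$data$variable == "X", ])
  expect_error(fit_parameters(one_var, sc$initial, sc$reactor, sc$schedule),
               "two state variables")
  one_day <- observation_set(obs$data[obs$data$day == 4, ])
  expect_error(fit_parameters(one_day, sc$initial, sc$reactor, sc$schedule),
               "two sampling days")
  expect_error(fit_parameters(obs, sc$initial, sc$reactor, sc$schedule,
                              freeze = "not_a_parameter"),
               "unknown parameter")
  # starting at the truth the objective is already (numerically) zero and
  # the simplex stops without moving away
  rep <- fit_parameters(obs, sc$initial, sc$reactor, sc$schedule,
                        init = ref_params, max_iter = 10)
  expect_lt(rep$nrmse, 0.1)
  expect_lt(rep$nrmse, rep$nrmse_trajectory[1] + 1e-9)
  expect_equal(rep$parameters$mu_max, ref_params$mu_max, tolerance = 0.02)
  # the report never violates the core invariants
  expect_s3_class(validate_parameters(rep$parameters), "kinetic_parameters")
})
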