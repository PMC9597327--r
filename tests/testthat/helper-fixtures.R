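# Shared fixtures: the reference flat-panel scenario and fast simulation
# settings used across test files. All fixtures are built in code.

ref_params <- kinetic_parameters()

ref_scenario <- scenario("5L_flat_panel_4xf2")

quick_sim <- function(p = ref_params, sc = ref_scenario, duration = sc$duration,
                      ...) {
  simulate_batch(sc$initial, sc$reactor, sc$schedule, p,
                 duration = duration, ...)
}

# Monte-Carlo oracle for the bubble-column average intensity: uniform
# sampling over the cross-section area, independent of the quadrature
# code path.
mc_column_average <- function(Io, Ka, X, R, n = 1e6, seed = 1) {
  set.seed(seed)
  r <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  l1 <- sqrt(R^2 - r^2 * cos(th)^2) - r * sin(th)
  l2 <- sqrt(R^2 - r^2 * cos(th)^2) + r * sin(th)
  l3 <- sqrt(R^2 - r^2 * sin(th)^2) - r * cos(th)
  v <- Io * (exp(-Ka * X * l1) + exp(-Ka * X * l2) + exp(-Ka * X * l3))
  list(mean = mean(v), se = sd(v) / sqrt(n))
}

# Perturb the free kinetic constants of `p` by up to +/- `mag` (relative),
# reproducibly.
perturb_params <- function(p, mag, seed, skip = character(0)) {
  set.seed(seed)
  for (nm in setdiff(kinetic_parameter_names(), skip))
    p[[nm]] <- p[[nm]] * runif(1, 1 - mag, 1 + mag)
  validate_parameters(p)
}
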