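test_that("local intensity follows Beer-Lambert attenuation", {
  expect_equal(local_intensity(350, 0.5, 0, 0.05), 350)
  expect_equal(local_intensity(350, 0.5, 100, 0), 350)
  # Io * e^-2.5
  expect_equal(local_intensity(350, 0.5, 100, 0.05), 28.72975,
               tolerance = 1e-5)
  expect_error(local_intensity(-1, 0.5, 100, 0.05), "non-negative")
  # monotone decreasing in each attenuating factor
  l <- seq(0, 0.05, length.out = 20)
  expect_true(all(diff(local_intensity(350, 0.5, 100, l)) < 0))
})

test_that("flat-panel average equals the closed form with a safe 0/0 limit", {
  expect_equal(average_intensity_flat_panel(350, 0.5, 0, 0.05), 350)
  # a = 2.5: Io (1 - e^-a)/a = 128.51
  expect_equal(average_intensity_flat_panel(350, 0.5, 100, 0.05), 128.5081,
               tolerance = 1e-5)
  # limit continuity at vanishing optical depth
  a_tiny <- average_intensity_flat_panel(350, 1e-12, 1, 1)
  expect_equal(a_tiny, 350, tolerance = 1e-9)
  expect_error(average_intensity_flat_panel(350, -0.1, 1, 1))
})

test_that("flat-panel average equals the numerical mean of the local profile", {
  set.seed(401)
  for (i in 1:20) {
    Io <- runif(1, 50, 1000); Ka <- runif(1, 0.1, 0.8)
    X <- runif(1, 0, 2000); L <- runif(1, 0.01, 0.2)
    num <- stats::integrate(function(l) local_intensity(Io, Ka, X, l),
                            0, L, rel.tol = 1e-10)$value / L
    expect_equal(average_intensity_flat_panel(Io, Ka, X, L), num,
                 tolerance = 1e-6)
  }
})

test_that("column average hits the 3 Io zero-biomass limit and decays to 0", {
  expect_equal(average_intensity_bubble_column(360, 0.3, 0, 0.095), 1080,
               tolerance = 1e-9)
  expect_lt(average_intensity_bubble_column(360, 10, 1e5, 0.095), 1e-3)
  expect_error(average_intensity_bubble_column(360, 0.3, -5, 0.095))
  # monotone decreasing in biomass
  X <- c(0, 50, 200, 500, 1000, 2000)
  v <- vapply(X, function(x)
    average_intensity_bubble_column(360, 0.3, x, 0.095), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("column quadrature is stable under grid doubling", {
  base <- average_intensity_bubble_column(360, 0.4, 800, 0.095,
                                          nr = 64, ntheta = 128)
  dbl <- average_intensity_bubble_column(360, 0.4, 800, 0.095,
                                         nr = 128, ntheta = 256)
  expect_equal(base, dbl, tolerance = 1e-4)
  expect_error(
    average_intensity_bubble_column(360, 0.4, 800, 0.095,
                                    nr = 4, ntheta = 8, tol = 1e-10),
    "not converged")
})

test_that("column quadrature agrees with a Monte-Carlo area-sampling oracle", {
  set.seed(402)
  for (i in 1:20) {
    Io <- runif(1, 100, 500)
    Ka <- runif(1, 0.2, 0.7)
    X <- runif(1, 0, 1500)
    R <- runif(1, 0.03, 0.15)
    mc <- mc_column_average(Io, Ka, X, R, n = 1e5, seed = i)
    quad <- average_intensity_bubble_column(Io, Ka, X, R)
    expect_lt(abs(quad - mc$mean), 3 * mc$se)
  }
})

test_that("the cached interpolator tracks direct evaluation within 0.5%", {
  reactor <- reactor_config("bubble_column", 360, photoperiod_light_h = 16)
  f <- make_iav_function(reactor)
  set.seed(403)
  for (i in 1:15) {
    Ka <- runif(1, 0.2, 0.7); X <- runif(1, 0, 2500)
    direct <- average_intensity_bubble_column(360, Ka, X, 0.095)
    expect_equal(f(Ka, X), direct, tolerance = 5e-3)
  }
  # flat-panel branch is the exact closed form
  fp <- make_iav_function(ref_scenario$reactor)
  expect_equal(fp(0.5, 100), average_intensity_flat_panel(350, 0.5, 100, 0.05))
})

test_that("radial profile helper writes a polar intensity table", {
  f <- withr::local_tempfile(fileext = ".csv")
  prof <- column_intensity_profile(360, 0.3, 500, 0.095, nr = 5, ntheta = 8,
                                   file = f)
  expect_true(file.exists(f))
  expect_named(prof, c("r", "theta", "intensity"))
  expect_true(all(prof$intensity >= 0 & prof$intensity <= 3 * 360))
})
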