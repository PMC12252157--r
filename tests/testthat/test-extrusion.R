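test_that("nozzle geometry maps gauges to bores and validates inputs", {
  nz25 <- nozzle_geometry(25)
  expect_equal(nz25$inner_diameter, 0.250)
  expect_identical(nz25$radius, nz25$inner_diameter / 2)
  expect_equal(nozzle_geometry(27)$inner_diameter, 0.210)
  expect_error(nozzle_geometry(30), "lookup table")
  custom <- nozzle_geometry(30, table = c("30" = 0.159))
  expect_equal(custom$inner_diameter, 0.159)
  expect_error(nozzle_geometry(inner_diameter = -1), "positive")
  expect_false(nozzle_geometry(25, channel_length = 20)$channel_length_default)
})

test_that("flow rate is velocity times bore area", {
  nz <- nozzle_geometry(25)
  expect_equal(flow_rate(0, nz), 0)
  expect_equal(flow_rate(25, nz), 25 * pi * 0.125^2, tolerance = 1e-12)
  big <- nozzle_geometry(inner_diameter = 0.5)
  expect_equal(flow_rate(10, big) / flow_rate(10, nz), 4, tolerance = 1e-12)
  expect_error(flow_rate(-1, nz), "non-negative")
})

test_that("maximum velocity follows the (3n+1)/n profile factor", {
  expect_equal(max_velocity(10, 1), 40)
  expect_equal(max_velocity(10, 0.5), 50)
  expect_equal(max_velocity(0, 0.7), 0)
  expect_error(max_velocity(10, 0), "positive")
  expect_error(max_velocity(10, -0.2), "positive")
  # the classical pipe-flow alternative
  expect_equal(max_velocity(10, 1, profile = "textbook"), 20)
  expect_equal(max_velocity(10, 0.5, profile = "textbook"), 10 * 2.5 / 1.5)
})

test_that("pressure drop is Hagen-Poiseuille in SI units", {
  expect_equal(pressure_drop(2.88, 0.025, 0.01, 1.25e-4), 368640)
  base <- pressure_drop(1, 0.01, 0.01, 1e-4)
  expect_equal(pressure_drop(2, 0.01, 0.01, 1e-4), 2 * base, tolerance = 1e-12)
  expect_equal(pressure_drop(1, 0.03, 0.01, 1e-4), 3 * base, tolerance = 1e-12)
  expect_equal(pressure_drop(1, 0.01, 0.05, 1e-4), 5 * base, tolerance = 1e-12)
  expect_equal(pressure_drop(1, 0.01, 0.01, 2e-4), base / 4, tolerance = 1e-12)
  expect_error(pressure_drop(0, 1, 1, 1), "positive")
  expect_error(pressure_drop(1, 0, 1, 1), "positive")
})

test_that("velocity-from-pressure and consistency index are exact inverses", {
  expect_equal(extrusion_velocity_from_pressure(1, 1, 1, 4, 1), 1)
  expect_equal(consistency_index(1, 1, 1, 4, 1), 1)
  set.seed(42)
  for (i in 1:200) {
    n <- runif(1, 0.2, 1.5); K <- 10^runif(1, -1, 3)
    R <- runif(1, 1e-5, 1e-3); dP <- 10^runif(1, 3, 6); L <- runif(1, 1e-3, 0.05)
    v <- extrusion_velocity_from_pressure(n, K, R, dP, L)
    expect_equal(consistency_index(n, R, v, dP, L), K, tolerance = 1e-12)
  }
  # linear in pressure drop
  v1 <- extrusion_velocity_from_pressure(0.4, 120, 1e-4, 1e5, 0.01)
  v2 <- extrusion_velocity_from_pressure(0.4, 120, 1e-4, 2e5, 0.01)
  expect_equal(v2 / v1, 2, tolerance = 1e-12)
  # K decreases as observed velocity increases
  ks <- sapply(c(1, 2, 5, 10), function(v) consistency_index(0.4, 1e-4, v, 1e5, 0.01))
  expect_true(all(diff(ks) < 0))
})

test_that("filament diameter reduces to the bore at n = 1 and shrinks with n", {
  nz <- nozzle_geometry(25)
  expect_equal(filament_diameter(nz, 25, 1, max_velocity(25, 1)),
               nz$inner_diameter, tolerance = 1e-15)
  expect_equal(filament_diameter(nz, 25, 0.4, max_velocity(25, 0.4)),
               4 * 0.250 / 2.2, tolerance = 1e-12)
  ns <- seq(0.2, 1.5, by = 0.1)
  dfs <- sapply(ns, function(n) filament_diameter(nz, 10, n, max_velocity(10, n)))
  expect_true(all(diff(dfs) < 0))
  expect_error(filament_diameter(nz, 0, 1, 4), "positive")
})

test_that("extrusion report chains the model and flags defaults", {
  cv <- generate_rheology(0.4, 120, seed = 3)
  rep <- extrusion_report(cv, nozzle_geometry(25), velocity = 25,
                          pressure = 170, temperature = 32)
  expect_equal(rep$n, 0.4, tolerance = 1e-6)
  expect_equal(rep$K, 120, tolerance = 1e-3)
  expect_gt(rep$flow_rate_mm3_s, 0)
  expect_gt(rep$pressure_drop_kPa, 0)
  expect_equal(rep$v_max_mm_s, 25 * (3 * 0.4 + 1) / 0.4, tolerance = 1e-5)
  expect_equal(rep$filament_diameter_mm, 4 * 0.250 / 2.2, tolerance = 1e-5)
  expect_true(rep$channel_length_default)
  # explicit viscosity overrides the power-law estimate
  rep2 <- extrusion_report(cv, nozzle_geometry(25), velocity = 25, eta = 2.88)
  expect_equal(rep2$eta_Pa_s, 2.88)
  expect_equal(rep2$pressure_drop_kPa,
               pressure_drop(2.88, 0.025, 0.0127, 1.25e-4) / 1000,
               tolerance = 1e-10)
})
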