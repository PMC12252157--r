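test_that("the full factorial design crosses every level", {
  d <- full_factorial_design(1)
  expect_equal(nrow(d), 50)
  expect_equal(nrow(unique(d[, c("nozzle_G", "pressure_kPa", "velocity_mm_s")])), 50)
  expect_setequal(unique(d$nozzle_G), c(27, 25))
  expect_setequal(unique(d$pressure_kPa), c(160, 170, 180, 190, 200))
  expect_setequal(unique(d$velocity_mm_s), c(5, 10, 15, 20, 25))
  expect_equal(sum(d$A_c), 0)
  expect_equal(sum(d$B_c), 0)
  expect_equal(sum(d$C_c), 0)
  expect_equal(nrow(full_factorial_design(17)), 850)
  expect_equal(anyDuplicated(full_factorial_design(3)$run_id), 0)
  expect_error(full_factorial_design(0), "positive integer")
})

test_that("fitting recovers a noiseless truth surface exactly", {
  runs <- generate_doe_responses(full_factorial_design(1),
                                 surface_truth(reference_model("eq19"), 0))
  m <- fit_factorial_model(runs, "filament_diameter_mm")
  truth <- reference_model("eq19")$coefficients
  for (nm in names(truth)) {
    expect_equal(unname(m$coefficients[nm]), unname(truth[nm]), tolerance = 1e-8)
  }
  expect_lt(abs(m$coefficients["BC"]), 1e-10)
  expect_lt(abs(m$coefficients["ABC"]), 1e-10)
})

test_that("fitted coefficients agree with the normal-equations oracle", {
  set.seed(23)
  runs <- full_factorial_design(2)
  runs$y <- 2 + 0.5 * runs$A_c - 0.03 * runs$B_c + 0.1 * runs$C_c +
    0.02 * runs$A_c * runs$B_c + rnorm(nrow(runs), 0, 0.2)
  m <- fit_factorial_model(runs, "y")
  # independent brute-force least squares
  X <- cbind(1, runs$A_c, runs$B_c, runs$C_c, runs$A_c * runs$B_c,
             runs$A_c * runs$C_c, runs$B_c * runs$C_c,
             runs$A_c * runs$B_c * runs$C_c)
  beta <- solve(t(X) %*% X, t(X) %*% runs$y)
  expect_equal(unname(m$coefficients), drop(beta), tolerance = 1e-10)
})

test_that("constant responses yield a null model", {
  runs <- full_factorial_design(1)
  runs$y <- 5
  m <- fit_factorial_model(runs, "y")
  expect_equal(unname(m$coefficients["(Intercept)"]), 5)
  expect_true(all(abs(m$coefficients[-1]) < 1e-12))
  expect_equal(m$r_squared, 0)
  pm <- prune_model(m)
  expect_length(pm$terms, 0)
})

test_that("missing design cells are reported by name", {
  runs <- full_factorial_design(1)
  runs <- runs[!(runs$nozzle_G == 27 & runs$pressure_kPa == 160 &
                   runs$velocity_mm_s == 5), ]
  runs$y <- 1
  expect_error(fit_factorial_model(runs, "y"), "27 160 5")
})

test_that("pruning keeps exactly the significant support", {
  # only-A truth
  runs <- full_factorial_design(2)
  set.seed(3)
  runs$y <- 1 + 0.8 * runs$A_c + rnorm(nrow(runs), 0, 0.05)
  pm <- prune_model(fit_factorial_model(runs, "y"))
  expect_identical(pm$terms, "A")
  expect_s3_class(pm$prune_trace, "data.frame")
  expect_equal(sum(pm$prune_trace$kept), 1)

  # truth surface with small noise keeps the generating support
  tr <- surface_truth(reference_model("eq19"), noise_sigma = 0.01)
  runs2 <- generate_doe_responses(full_factorial_design(1), tr, seed = 42)
  pm2 <- prune_model(fit_factorial_model(runs2, "filament_diameter_mm"))
  expect_identical(sort(pm2$terms), sort(c("A", "B", "C", "AB", "AC")))

  # alpha = 1 removes nothing
  m3 <- fit_factorial_model(runs2, "filament_diameter_mm")
  expect_length(prune_model(m3, alpha = 1)$terms, 7)
})

test_that("reference surfaces evaluate the printed coefficients", {
  eq19 <- reference_model("eq19")
  eq20 <- reference_model("eq20")
  expect_equal(predict(eq19, 26, 180, 15), 1.0980)
  expect_equal(predict(eq20, 26, 180, 15), 51.810)
  # an off-center point by hand
  expect_equal(predict(eq19, 27, 170, 25),
               1.0980 - 0.5492 * 1 + 0.0073 * (-10) - 0.0648 * 10 -
                 0.0088 * 1 * (-10) - 0.0403 * 1 * 10, tolerance = 1e-12)
  expect_error(prune_model(eq19), "reference")
})

test_that("prediction is linear in the retained monomials", {
  eq19 <- reference_model("eq19")
  # no BC term: prediction at a B-midpoint is the mean of its neighbors
  mid <- predict(eq19, 27, 180, seq(5, 25, by = 5))
  lo <- predict(eq19, 27, 170, seq(5, 25, by = 5))
  hi <- predict(eq19, 27, 190, seq(5, 25, by = 5))
  expect_equal(mid, (lo + hi) / 2, tolerance = 1e-12)
})

test_that("main effects equal balanced model averages", {
  runs <- generate_doe_responses(full_factorial_design(1),
                                 surface_truth(reference_model("eq19"), 0))
  me <- main_effects(runs, "filament_diameter_mm")
  a27 <- me$mean[me$factor == "nozzle_G" & me$level == 27]
  expect_equal(a27, 0.5488, tolerance = 1e-12)
  # level means average to the grand mean within each factor
  for (f in unique(me$factor)) {
    expect_equal(mean(me$mean[me$factor == f]),
                 mean(runs$filament_diameter_mm), tolerance = 1e-12)
  }
  # constant response: every level mean equals it
  runs$y <- 3.3
  me2 <- main_effects(runs, "y")
  expect_true(all(me2$mean == 3.3))
  # unbalanced data warns
  expect_warning(main_effects(runs[-1, ], "y"), "unbalanced")
})

test_that("OLS two-level effects equal cell-mean contrasts", {
  set.seed(77)
  for (rep in 1:5) {
    runs <- full_factorial_design(sample(1:3, 1))
    runs$y <- rnorm(nrow(runs))
    m <- fit_factorial_model(runs, "y")
    # for the two-level factor, the centered slope is half the difference
    # of level means (levels coded -1 / +1)
    m27 <- mean(runs$y[runs$nozzle_G == 27])
    m25 <- mean(runs$y[runs$nozzle_G == 25])
    expect_equal(unname(m$coefficients["A"]), (m27 - m25) / 2, tolerance = 1e-10)
    expect_equal(unname(m$coefficients["(Intercept)"]) +
                   unname(m$coefficients["A"]), m27, tolerance = 1e-10)
  }
})

test_that("response surface grids evaluate the model over factor ranges", {
  eq19 <- reference_model("eq19")
  g1 <- response_surface_grid(eq19, c("A", "C"), n = 1)
  expect_equal(g1$prediction, predict(eq19, g1$A, 180, g1$C))
  g <- response_surface_grid(eq19, c("A", "C"), n = 11)
  # diameter decreases with velocity at the 27G nozzle (combined C slope
  # -0.0648 - 0.0403 < 0)
  d27 <- g$prediction[abs(g$A - 27) < 1e-9]
  expect_true(all(diff(d27[order(g$C[abs(g$A - 27) < 1e-9])]) < 0))
  # no BC term: at fixed A the surface over (B, C) is linear in B
  g2 <- response_surface_grid(reference_model("eq20"), c("B", "C"),
                              fixed_level = 25, n = 5)
  for (cv in unique(g2$C)) {
    p <- g2$prediction[g2$C == cv][order(g2$B[g2$C == cv])]
    expect_lt(max(abs(diff(diff(p)))), 1e-10)
  }
  expect_error(response_surface_grid(eq19, c("A", "A")), "distinct")
})

test_that("comparison statistics match their definitions", {
  y <- c(1, 2, 3, 4); yh <- c(1.5, 2, 2, 5)
  expect_equal(mae(y, y), 0)
  expect_equal(mse(y, y), 0)
  expect_equal(mae(y, yh), mean(c(0.5, 0, 1, 1)))
  expect_equal(mse(y, yh), mean(c(0.25, 0, 1, 1)))
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(4, 1, 3, 2)), -0.4)
  expect_equal(pearson_r(y, yh), pearson_r(yh, y))
  expect_equal(pearson_r(y, 3 * yh + 2), pearson_r(y, yh), tolerance = 1e-12)
  expect_error(pearson_r(y, rep(1, 4)), "constant")
  expect_error(mae(y, c(1, 2)), "unequal")
})
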