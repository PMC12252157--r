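test_that("ssim satisfies identity, symmetry and range", {
  x <- pattern_image(32)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  y <- pmin(pmax(0.7 * x + 0.15 + 0.1 * sin(outer(1:32, 1:32, "+") / 5), 0), 1)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-14)
  set.seed(8)
  for (i in 1:10) {
    a <- matrix(runif(16 * 16), 16)
    b <- matrix(runif(16 * 16), 16)
    s <- ssim(a, b)
    expect_lte(abs(s), 1)
    expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  }
  expect_error(ssim(x, x[1:16, 1:16]), "identical shape")
})

test_that("ssim matches the windowed reference implementation", {
  # frozen oracle: scikit-image structural_similarity, win_size 7/5,
  # data_range 1, uniform windows, sample covariance
  x <- pattern_image(32)
  y <- pmin(pmax(0.7 * x + 0.15 + 0.1 * sin(outer(1:32, 1:32, "+") / 5), 0), 1)
  expect_equal(ssim(x, y), 0.9242277571, tolerance = 1e-9)
  expect_equal(ssim(x, y, window = 5), 0.9269961835, tolerance = 1e-9)
})

test_that("ssim closed form holds for constant images", {
  a <- matrix(0.2, 16, 16); b <- matrix(0.4, 16, 16)
  c1 <- 1e-4; c2 <- 9e-4
  expected <- (2 * 0.2 * 0.4 + c1) / (0.2^2 + 0.4^2 + c1) # variance factor = 1
  expect_equal(ssim(a, b, c1 = c1, c2 = c2), expected, tolerance = 1e-12)
})

test_that("ssim orders inverted images below identity", {
  x <- cbind(matrix(0, 16, 8), matrix(1, 16, 8))
  expect_lt(ssim(x, 1 - x), ssim(x, x))
})

test_that("the as-printed ssim variant breaks the identity on gray images", {
  x <- pattern_image(32)
  expect_lt(ssim(x, x, as_printed = TRUE), 1)
})

test_that("scale factors are objective/measured ratios", {
  cad <- cad_spec(10, 10, 0.25)
  expect_equal(scale_factors(mesh_measurement(10, 10, 0.25), cad),
               c(scale_l = 1, scale_w = 1))
  sf <- scale_factors(mesh_measurement(11.028, 11.044, 1.098), cad)
  expect_equal(unname(sf["scale_l"]), 10 / 11.028, tolerance = 1e-12)
  expect_equal(unname(sf["scale_w"]), 10 / 11.044, tolerance = 1e-12)
})

test_that("dimensional similarity penalizes absolute deviations", {
  cad <- cad_spec(10, 10, 0.25)
  expect_equal(dimensional_similarity(mesh_measurement(10, 10, 0.25), cad), 100)
  expect_equal(dimensional_similarity(mesh_measurement(11, 11, 0.25), cad), 80)
  # undershoot penalized identically to overshoot
  expect_equal(dimensional_similarity(mesh_measurement(9, 9, 0.25), cad), 80)
  sds <- sapply(seq(10, 14, by = 0.5), function(L)
    dimensional_similarity(mesh_measurement(L, 10, 0.25), cad))
  expect_true(all(diff(sds) < 0))
  # clamped at zero for extreme deviation
  expect_equal(dimensional_similarity(mesh_measurement(30, 30, 0.25), cad), 0)
})

test_that("aggregate similarity is the mean of its two components", {
  expect_equal(aggregate_similarity(100, 100), 100)
  expect_equal(aggregate_similarity(80, 90), 85)
  expect_equal(aggregate_similarity(90, 80), aggregate_similarity(80, 90))
  expect_error(aggregate_similarity(101, 50), "exceed 100")
})

test_that("percent errors and manual similarity follow the error chain", {
  cad <- cad_spec(10, 10, 0.25)
  expect_equal(unname(percent_errors(mesh_measurement(10, 10, 0.25), cad)),
               c(0, 0, 0))
  e <- percent_errors(mesh_measurement(11.028, 10, 0.25), cad)
  expect_equal(unname(e["e_l"]), 10.28, tolerance = 1e-9)
  over <- percent_errors(mesh_measurement(11, 10, 0.25), cad)
  under <- percent_errors(mesh_measurement(9, 10, 0.25), cad)
  expect_equal(over, under)

  expect_equal(normalized_error(0, 0, 0), 0)
  expect_equal(normalized_error(3, 6, 0), 3)
  expect_equal(normalized_error(6, 0, 3), 3)
  expect_equal(normalized_error(1, 2, 3, literal = TRUE), 200)

  expect_equal(manual_similarity(0), 100)
  expect_equal(manual_similarity(3), 97)
  expect_equal(manual_similarity(150), 0)
})

test_that("perfect print identities chain to 100", {
  cad <- cad_spec(10, 10, 0.25)
  m <- mesh_measurement(10, 10, 0.25)
  e <- percent_errors(m, cad)
  expect_equal(manual_similarity(normalized_error(e["e_l"], e["e_w"], e["e_fd"])),
               100, ignore_attr = TRUE)
  expect_equal(aggregate_similarity(100, dimensional_similarity(m, cad)), 100)
})

test_that("all similarity outputs stay in [0, 100] under fuzzing", {
  set.seed(31)
  cad <- cad_spec(10, 10, 0.25)
  for (i in 1:50) {
    m <- mesh_measurement(runif(1, 0.1, 40), runif(1, 0.1, 40), runif(1, 0.01, 6))
    sdv <- dimensional_similarity(m, cad)
    e <- percent_errors(m, cad)
    man <- manual_similarity(normalized_error(e["e_l"], e["e_w"], e["e_fd"]))
    expect_gte(sdv, 0); expect_lte(sdv, 100)
    expect_gte(man, 0); expect_lte(man, 100)
    sa <- aggregate_similarity(runif(1, -100, 100), sdv)
    expect_lte(sa, 100)
  }
})

test_that("scoring a mesh rendered exactly at CAD spec is near-perfect", {
  cad <- cad_spec(10, 10, 0.25)
  r <- render_mesh(mesh_render_spec(cad = cad, seed = 2))
  sc <- score_print(r$image, cad)
  expect_gte(sc$sa, 99)
  expect_gte(sc$sd, 99)
  expect_gte(sc$manual_similarity, 99)
  expect_gte(sc$ssim_pct, 99)
})
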