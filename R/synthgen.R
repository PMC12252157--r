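# Synthetic-data generators. Every generator is a pure function of its
# spec plus seed, so fixtures are rebuilt bit-identically at test time
# instead of being shipped.

#' Specification for rendering a synthetic printed mesh
#'
#' Describes an orthogonal strand-grid scaffold to rasterize: the CAD
#' target, strand width, strand pitch, image geometry, and the controlled
#' imperfections (randomly removed strand segments, an additive
#' dimensional bias, intensity noise). Defaults emulate the calibration
#' mesh used throughout: a 10 mm x 10 mm, 5 x 5 strand grid of 0.25 mm
#' strands (a 25G bore) imaged at 0.05 mm/px.
#'
#' @param cad a [cad_spec()] (default 10 x 10 mm, 0.25 mm strands).
#' @param strand_width strand width, mm; defaults to the CAD filament
#'   diameter. Must be smaller than `grid_pitch`.
#' @param grid_pitch center-to-center strand spacing, mm; default spaces
#'   5 strands across the mesh.
#' @param image_size square image side, px (default 256).
#' @param mm_per_pixel physical pixel size (default 0.05 mm).
#' @param defect_rate fraction of strand segments removed in \[0, 1\].
#' @param dimension_bias additive error on the printed length/width, mm
#'   (positive = overextrusion/spread).
#' @param noise_sigma Gaussian intensity noise sd.
#' @param seed integer; fixes the render bit-exactly.
#' @return An object of class `mesh_render_spec`.
#' @export
mesh_render_spec <- function(cad = cad_spec(10, 10, 0.25),
                             strand_width = cad$filament_diameter,
                             grid_pitch = (cad$length - strand_width) / 4,
                             image_size = 256, mm_per_pixel = 0.05,
                             defect_rate = 0, dimension_bias = 0,
                             noise_sigma = 0, seed = 1) {
  stopifnot(inherits(cad, "cad_spec"))
  check_positive(strand_width, "strand_width")
  check_positive(grid_pitch, "grid_pitch")
  check_positive(image_size, "image_size")
  check_positive(mm_per_pixel, "mm_per_pixel")
  if (strand_width >= grid_pitch) {
    stop_domain("strand_width (%g) must be smaller than grid_pitch (%g)",
                strand_width, grid_pitch)
  }
  if (defect_rate < 0 || defect_rate > 1) stop_domain("defect_rate must be in [0, 1]")
  structure(
    list(cad = cad, strand_width = strand_width, grid_pitch = grid_pitch,
         image_size = as.integer(image_size), mm_per_pixel = mm_per_pixel,
         defect_rate = defect_rate, dimension_bias = dimension_bias,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "mesh_render_spec"
  )
}

# pixel index range whose centers fall inside [a, b) mm, given scale m
px_range <- function(a, b, m, lim) {
  i1 <- max(1L, as.integer(ceiling(a / m + 0.5 - 1e-9)))
  i2 <- min(lim, as.integer(floor(b / m + 0.5 - 1e-9)))
  if (i2 < i1) integer(0) else i1:i2
}

#' Render a synthetic printed mesh with ground truth
#'
#' Rasterizes the strand grid described by the spec, removes a seeded
#' random fraction of strand segments (segments span crossing-to-crossing,
#' so `defect_rate = 1` empties the image), adds Gaussian intensity noise
#' and returns the image together with the ground-truth measurement
#' (length/width including the dimensional bias, strand width).
#'
#' @param spec a [mesh_render_spec()].
#' @return List with `image` (a [print_image()]) and `truth`
#'   (a [mesh_measurement()]).
#' @examples
#' r <- render_mesh(mesh_render_spec(seed = 7))
#' r$truth
#' @export
render_mesh <- function(spec) {
  stopifnot(inherits(spec, "mesh_render_spec"))
  set.seed(spec$seed)
  m <- spec$mm_per_pixel
  S <- spec$image_size
  w <- spec$strand_width
  if (w / m < 1) {
    stop_domain("strand width %g mm is under 1 px at %g mm/px; use a finer scale",
                w, m)
  }
  L <- spec$cad$length + spec$dimension_bias
  W <- spec$cad$width + spec$dimension_bias
  if (L <= w || W <= w) stop_domain("mesh dimensions too small for the strand width")
  if (L > S * m || W > S * m) {
    stop_domain("mesh (%g x %g mm) exceeds the %g mm field; enlarge image_size",
                L, W, S * m)
  }
  n_len <- max(2L, as.integer(floor((spec$cad$length - w) / spec$grid_pitch + 1e-9)) + 1L)
  n_wid <- max(2L, as.integer(floor((spec$cad$width - w) / spec$grid_pitch + 1e-9)) + 1L)
  # strand centerlines spread over the realized (biased) dimensions
  hc <- w / 2 + (seq_len(n_len) - 1) * (L - w) / (n_len - 1) # along length (rows)
  vc <- w / 2 + (seq_len(n_wid) - 1) * (W - w) / (n_wid - 1) # along width (cols)
  off_y <- (S * m - L) / 2
  off_x <- (S * m - W) / 2
  # segments: horizontal strands cut at vertical-strand centers (ends merged
  # into the first/last segment), and vice versa
  hb <- c(0, vc[-c(1, n_wid)], W)
  vb <- c(0, hc[-c(1, n_len)], L)
  segs <- list()
  for (j in seq_len(n_len)) {
    for (k in seq_len(length(hb) - 1)) {
      segs[[length(segs) + 1]] <- c(y0 = hc[j] - w / 2, y1 = hc[j] + w / 2,
                                    x0 = hb[k], x1 = hb[k + 1])
    }
  }
  for (i in seq_len(n_wid)) {
    for (k in seq_len(length(vb) - 1)) {
      segs[[length(segs) + 1]] <- c(y0 = vb[k], y1 = vb[k + 1],
                                    x0 = vc[i] - w / 2, x1 = vc[i] + w / 2)
    }
  }
  n_seg <- length(segs)
  drop_n <- round(spec$defect_rate * n_seg)
  keep <- rep(TRUE, n_seg)
  if (drop_n > 0) keep[sample.int(n_seg, drop_n)] <- FALSE
  img <- matrix(0, S, S)
  for (s in segs[keep]) {
    ri <- px_range(s["y0"] + off_y, s["y1"] + off_y, m, S)
    ci <- px_range(s["x0"] + off_x, s["x1"] + off_x, m, S)
    if (length(ri) && length(ci)) img[ri, ci] <- 1
  }
  if (spec$noise_sigma > 0) {
    img <- pmin(pmax(img + rnorm(length(img), 0, spec$noise_sigma), 0), 1)
  }
  list(
    image = print_image(img, m, source_id = sprintf("synthetic-mesh-seed%d", spec$seed)),
    truth = mesh_measurement(L, W, w)
  )
}

#' Generate a synthetic power-law rheology flow curve
#'
#' Viscosity follows \eqn{\eta = K \dot\gamma^{n-1}} on log-spaced shear
#' rates, with multiplicative lognormal noise:
#' \eqn{\eta_i = K \dot\gamma_i^{n-1} e^{\epsilon_i}},
#' \eqn{\epsilon_i \sim N(0, \sigma^2)}.
#'
#' @param n flow-behavior index (> 0; < 1 gives shear thinning).
#' @param K consistency index, Pa·s^n (> 0).
#' @param rate_range shear-rate range `c(lo, hi)` in 1/s.
#' @param points number of points (default 30).
#' @param noise_sigma lognormal sigma (0 = noiseless).
#' @param seed integer seed.
#' @param temperature metadata, degrees C.
#' @return A [rheology_curve()].
#' @export
generate_rheology <- function(n, K, rate_range = c(0.1, 100), points = 30,
                              noise_sigma = 0, seed = 1, temperature = 32) {
  check_positive(n, "n"); check_positive(K, "K")
  if (length(rate_range) != 2 || any(rate_range <= 0) ||
      rate_range[1] >= rate_range[2]) {
    stop_domain("`rate_range` must be an increasing positive pair")
  }
  set.seed(seed)
  rate <- exp(seq(log(rate_range[1]), log(rate_range[2]), length.out = points))
  eta <- K * rate^(n - 1)
  if (noise_sigma > 0) eta <- eta * exp(rnorm(points, 0, noise_sigma))
  rheology_curve(rate, eta, temperature = temperature)
}

#' Truth surface for synthetic factorial responses
#'
#' A centered-coded polynomial surface plus Gaussian noise, used as the
#' generating truth for synthetic DoE response tables. Defaults to the
#' shipped reference surfaces; when `noise_sigma` is `NULL` it is derived
#' in closed form from the surface's reported R-squared over the full
#' design: \eqn{\sigma^2 = V_{truth} (1 - R^2) / R^2}, where
#' \eqn{V_{truth}} is the population variance of the surface across the
#' 50 design cells. This makes a simulated fit at the generated noise
#' level reproduce the reported fit quality in expectation.
#'
#' @param model a `factorial_model` truth surface (default
#'   `reference_model("eq19")`).
#' @param noise_sigma response noise sd; `NULL` derives it from the
#'   model's R-squared as above.
#' @return An object of class `surface_truth`.
#' @export
surface_truth <- function(model = reference_model("eq19"), noise_sigma = NULL) {
  stopifnot(inherits(model, "factorial_model"))
  if (is.null(noise_sigma)) {
    d <- full_factorial_design(1)
    mu <- predict(model, d$nozzle_G, d$pressure_kPa, d$velocity_mm_s)
    v_truth <- mean((mu - mean(mu))^2)
    r2 <- model$r_squared
    if (is.na(r2) || r2 <= 0 || r2 >= 1) {
      stop_domain("cannot derive noise from R^2 = %s; give noise_sigma", r2)
    }
    noise_sigma <- sqrt(v_truth * (1 - r2) / r2)
  }
  structure(list(model = model, response_name = model$response_name,
                 noise_sigma = noise_sigma),
            class = "surface_truth")
}

#' Generate factorial responses from a truth surface
#'
#' Adds seeded Gaussian noise to the truth surface evaluated at every
#' run of the design.
#'
#' @param design a [full_factorial_design()] (or compatible data.frame).
#' @param truth a [surface_truth()].
#' @param seed integer seed.
#' @return The design with the response column appended.
#' @export
generate_doe_responses <- function(design, truth = surface_truth(), seed = 1) {
  stopifnot(inherits(truth, "surface_truth"))
  set.seed(seed)
  mu <- predict(truth$model, design$nozzle_G, design$pressure_kPa,
                design$velocity_mm_s)
  design[[truth$response_name]] <-
    mu + rnorm(nrow(design), 0, truth$noise_sigma)
  design
}

#' Generate a labeled synthetic print-image dataset
#'
#' Draws mesh images from a two-component quality mixture — "good" prints
#' (few missing segments, small dimensional bias) and "bad" prints (many
#' broken strands, large bias) — scores each against the CAD design with
#' the fidelity metrics, labels them High/Low by the aggregate-similarity
#' threshold, and joins each image to a run of the factorial experiment
#' matrix. Images are returned preprocessed (binary, `target_size`).
#'
#' @param n_images number of images (>= 2).
#' @param quality_mixture probabilities `c(good, bad)` (default 50/50).
#' @param cad the CAD target (default 10 x 10 mm, 0.25 mm strands).
#' @param seed integer seed; fixes the whole dataset.
#' @param sa_threshold aggregate-similarity cutoff for the High label
#'   (default 70).
#' @param image_size render size, px (default 256).
#' @param mm_per_pixel render scale (default 0.05).
#' @param target_size preprocessed size (default `c(128, 128)`).
#' @param plant_perfect if `TRUE`, one seeded-random image is rendered
#'   exactly at CAD spec (zero defects/bias/noise), planting a known
#'   optimum; its index is flagged in the manifest.
#' @param good,bad named lists overriding the mixture components'
#'   parameter ranges (`defect`, `bias_sd` or `bias_range`, `noise`).
#' @return An object of class `labeled_dataset`: `images`
#'   (target x target x n array), `manifest` (data.frame with `image_id`,
#'   `run_id`, `label`, `sa_pct`, `ssim_pct`, `sd_pct`,
#'   `manual_similarity_pct`, `quality`, `is_planted`), `design` (the
#'   experiment matrix), `cad`, `sa_threshold`.
#' @export
generate_labeled_dataset <- function(n_images, quality_mixture = c(0.5, 0.5),
                                     cad = cad_spec(10, 10, 0.25), seed = 1,
                                     sa_threshold = 70, image_size = 256,
                                     mm_per_pixel = 0.05,
                                     target_size = c(128, 128),
                                     plant_perfect = FALSE,
                                     good = list(defect = c(0, 0.05),
                                                 bias_sd = 0.1, noise = 0.05),
                                     bad = list(defect = c(0.3, 0.6),
                                                bias_range = c(1.5, 3),
                                                noise = 0.08)) {
  if (n_images < 2) stop_domain("n_images must be >= 2")
  if (length(quality_mixture) != 2 || any(quality_mixture < 0) ||
      sum(quality_mixture) <= 0) {
    stop_domain("quality_mixture must be two non-negative weights")
  }
  set.seed(seed)
  design <- full_factorial_design(ceiling(n_images / 50))
  design <- design[seq_len(n_images), , drop = FALSE]
  quality <- sample(c("good", "bad"), n_images, replace = TRUE,
                    prob = quality_mixture / sum(quality_mixture))
  defect <- ifelse(quality == "good",
                   runif(n_images, good$defect[1], good$defect[2]),
                   runif(n_images, bad$defect[1], bad$defect[2]))
  bias <- ifelse(quality == "good",
                 rnorm(n_images, 0, good$bias_sd),
                 sample(c(-1, 1), n_images, replace = TRUE) *
                   runif(n_images, bad$bias_range[1], bad$bias_range[2]))
  # bias must keep the mesh inside the field and wider than a strand
  field <- image_size * mm_per_pixel
  bias <- pmin(pmax(bias, -0.8 * min(cad$length, cad$width)),
               field - max(cad$length, cad$width) - 0.2)
  noise <- ifelse(quality == "good", good$noise, bad$noise)
  planted <- rep(FALSE, n_images)
  if (plant_perfect) {
    pi_ <- sample.int(n_images, 1)
    planted[pi_] <- TRUE
    defect[pi_] <- 0; bias[pi_] <- 0; noise[pi_] <- 0
    quality[pi_] <- "good"
  }
  seeds <- sample.int(.Machine$integer.max - 1, n_images)

  ref <- render_mesh(mesh_render_spec(cad = cad, image_size = image_size,
                                      mm_per_pixel = mm_per_pixel, seed = 1L))
  ref_pre <- preprocess_image(ref$image, target_size)

  imgs <- array(0, dim = c(target_size[1], target_size[2], n_images))
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- mesh_render_spec(cad = cad, image_size = image_size,
                           mm_per_pixel = mm_per_pixel,
                           defect_rate = defect[i], dimension_bias = bias[i],
                           noise_sigma = noise[i], seed = seeds[i])
    r <- render_mesh(sp)
    pre <- preprocess_image(r$image, target_size)
    imgs[, , i] <- pre$pixels
    s <- ssim(pre, ref_pre)
    s_pct <- clamp_pct(100 * s)
    sd_pct <- dimensional_similarity(r$truth, cad)
    sa <- clamp_pct(aggregate_similarity(s_pct, sd_pct))
    errs <- percent_errors(r$truth, cad)
    man <- manual_similarity(normalized_error(errs["e_l"], errs["e_w"],
                                              errs["e_fd"]))
    rows[[i]] <- data.frame(
      image_id = i, run_id = design$run_id[i],
      label = as.integer(sa >= sa_threshold), sa_pct = sa,
      ssim_pct = s_pct, sd_pct = sd_pct, manual_similarity_pct = man,
      quality = quality[i], defect_rate = defect[i],
      dimension_bias_mm = bias[i], is_planted = planted[i])
  }
  manifest <- do.call(rbind, rows)
  if (length(unique(manifest$label)) < 2) {
    stop_domain(paste0(
      "the mixture produced a single class at sa_threshold = %g ",
      "(SA range %.1f-%.1f); adjust the threshold or mixture"),
      sa_threshold, min(manifest$sa_pct), max(manifest$sa_pct))
  }
  structure(
    list(images = imgs, manifest = manifest, design = design, cad = cad,
         sa_threshold = sa_threshold, seed = seed),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d images (%dx%d), %d High / %d Low (SA threshold %g%%)\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              sum(x$manifest$label == 1), sum(x$manifest$label == 0),
              x$sa_threshold))
  invisible(x)
}
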