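#' CAD target specification
#'
#' The design the printer is asked to produce: overall mesh length and
#' width, and the target strand (filament) diameter.
#'
#' @param length target length, mm (> 0).
#' @param width target width, mm (> 0).
#' @param filament_diameter target strand width, mm (> 0).
#' @return An object of class `cad_spec`.
#' @examples
#' cad_spec(10, 10, 0.25)
#' @export
cad_spec <- function(length, width, filament_diameter) {
  check_positive(length, "length")
  check_positive(width, "width")
  check_positive(filament_diameter, "filament_diameter")
  structure(list(length = length, width = width,
                 filament_diameter = filament_diameter),
            class = "cad_spec")
}

#' Physical measurement of a printed mesh
#'
#' Caliper-style measurements of one print: overall length, width and
#' strand (filament) diameter.
#'
#' @param length measured length, mm (> 0).
#' @param width measured width, mm (> 0).
#' @param filament_diameter measured strand diameter, mm (> 0).
#' @return An object of class `mesh_measurement`.
#' @export
mesh_measurement <- function(length, width, filament_diameter) {
  check_positive(length, "length")
  check_positive(width, "width")
  check_positive(filament_diameter, "filament_diameter")
  structure(list(length = length, width = width,
                 filament_diameter = filament_diameter),
            class = "mesh_measurement")
}

#' @export
print.mesh_measurement <- function(x, ...) {
  cat(sprintf("<mesh_measurement> L = %.3f mm, W = %.3f mm, F_D = %.3f mm\n",
              x$length, x$width, x$filament_diameter))
  invisible(x)
}

#' Image scale-calibration factors
#'
#' Ratios of objective (CAD) to measured dimensions, used to rescale
#' images so physical measurements and pixel measurements agree:
#' `Scale_L = L_objective / L`, `Scale_W = W_objective / W`.
#'
#' @param measured a [mesh_measurement()].
#' @param objective a [cad_spec()].
#' @return Named numeric vector `c(scale_l, scale_w)`.
#' @export
scale_factors <- function(measured, objective) {
  stopifnot(inherits(measured, "mesh_measurement"), inherits(objective, "cad_spec"))
  c(scale_l = objective$length / measured$length,
    scale_w = objective$width / measured$width)
}

#' Structural similarity index (SSIM) between two images
#'
#' Windowed SSIM: the mean over sliding windows of
#' \deqn{\frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'            {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with uniform windows (default 7 x 7), sample (n-1) normalization for the
#' variance/covariance terms, and the border of half a window cropped
#' before averaging. Defaults follow the common convention
#' \eqn{C_1 = (0.01 D)^2}, \eqn{C_2 = (0.03 D)^2} for dynamic range D.
#'
#' `as_printed = TRUE` reproduces a variant whose second denominator
#' factor is \eqn{(\mu_x^2 + \mu_y^2 + C_2)} instead of the variance sum;
#' that variant does not satisfy `ssim(x, x) = 1` for general images and
#' is provided for comparison only.
#'
#' @param x,y [print_image()]s or numeric matrices of identical shape with
#'   values in \[0, 1\].
#' @param c1,c2 stabilization constants.
#' @param window odd window side length in pixels (default 7).
#' @param dynamic_range data range D used for the default constants.
#' @param as_printed use the non-standard denominator variant.
#' @return SSIM index in \[-1, 1\].
#' @examples
#' m <- matrix(runif(64 * 64), 64)
#' ssim(m, m) # exactly 1
#' @export
ssim <- function(x, y, c1 = NULL, c2 = NULL, window = 7,
                 dynamic_range = 1, as_printed = FALSE) {
  gx <- if (inherits(x, "print_image")) x$pixels else x
  gy <- if (inherits(y, "print_image")) y$pixels else y
  if (!is.matrix(gx) || !is.matrix(gy)) stop_domain("ssim needs matrices or print_images")
  if (!all(dim(gx) == dim(gy))) stop_domain("ssim inputs must have identical shape")
  if (window %% 2 != 1 || window < 3) stop_domain("`window` must be an odd integer >= 3")
  if (any(dim(gx) < window)) stop_domain("images smaller than the %dx%d window", window, window)
  if (is.null(c1)) c1 <- (0.01 * dynamic_range)^2
  if (is.null(c2)) c2 <- (0.03 * dynamic_range)^2
  np <- window^2
  cov_norm <- np / (np - 1)
  kern <- matrix(1 / np, window, window)
  f2 <- function(m) as.matrix(EBImage::filter2(EBImage::Image(m), kern))
  mx <- f2(gx); my <- f2(gy)
  vx <- cov_norm * (f2(gx * gx) - mx * mx)
  vy <- cov_norm * (f2(gy * gy) - my * my)
  vxy <- cov_norm * (f2(gx * gy) - mx * my)
  den2 <- if (as_printed) mx^2 + my^2 + c2 else vx + vy + c2
  smap <- ((2 * mx * my + c1) * (2 * vxy + c2)) / ((mx^2 + my^2 + c1) * den2)
  pad <- (window - 1) / 2
  ri <- (pad + 1):(nrow(smap) - pad)
  ci <- (pad + 1):(ncol(smap) - pad)
  mean(smap[ri, ci])
}

clamp_pct <- function(x) pmin(pmax(x, 0), 100)

#' Dimensional similarity of a print to its CAD target
#'
#' \deqn{S_D = 100 - \frac{|L - L_O| + |W - W_O|}{\max(L_O, W_O)} \times 100}
#' Absolute deviations are used for both axes so that undershoot and
#' overshoot are penalized alike; the result is clamped to \[0, 100\].
#'
#' @param measured a [mesh_measurement()].
#' @param objective a [cad_spec()].
#' @return Dimensional similarity, percent.
#' @examples
#' dimensional_similarity(mesh_measurement(11, 11, 0.25), cad_spec(10, 10, 0.25)) # 80
#' @export
dimensional_similarity <- function(measured, objective) {
  stopifnot(inherits(measured, "mesh_measurement"), inherits(objective, "cad_spec"))
  dev <- abs(measured$length - objective$length) + abs(measured$width - objective$width)
  clamp_pct(100 - dev / max(objective$length, objective$width) * 100)
}

#' Aggregate similarity
#'
#' The mean of SSIM expressed as a percentage and the dimensional
#' similarity: \eqn{S_A = (SSIM\% + S_D) / 2}.
#'
#' @param ssim_pct SSIM in percent (<= 100).
#' @param sd_pct dimensional similarity in percent (<= 100).
#' @return Aggregate similarity, percent.
#' @export
aggregate_similarity <- function(ssim_pct, sd_pct) {
  if (any(ssim_pct > 100) || any(sd_pct > 100)) {
    stop_domain("similarity components cannot exceed 100")
  }
  (ssim_pct + sd_pct) / 2
}

#' Percentage errors of a print against CAD
#'
#' \eqn{E_L = |L_m - L_{CAD}| / L_{CAD} \times 100}, and analogously for
#' width and filament diameter.
#'
#' @param measured a [mesh_measurement()].
#' @param cad a [cad_spec()].
#' @return Named vector `c(e_l, e_w, e_fd)` in percent.
#' @export
percent_errors <- function(measured, cad) {
  stopifnot(inherits(measured, "mesh_measurement"), inherits(cad, "cad_spec"))
  c(e_l = abs(measured$length - cad$length) / cad$length * 100,
    e_w = abs(measured$width - cad$width) / cad$width * 100,
    e_fd = abs(measured$filament_diameter - cad$filament_diameter) /
      cad$filament_diameter * 100)
}

#' Normalized dimensional error
#'
#' The mean of the three percentage errors (length, width, filament
#' diameter). `literal = TRUE` applies the formula exactly as printed in
#' the source model, `E_D = (E_L + E_W + E_FD) / 3 * 100`, which
#' double-scales inputs that are already percentages; the default treats
#' the inputs as percentages and averages them.
#'
#' @param e_l,e_w,e_fd percentage errors (>= 0).
#' @param literal use the double-scaling literal form.
#' @return Normalized error `E_D`, percent.
#' @export
normalized_error <- function(e_l, e_w, e_fd, literal = FALSE) {
  check_positive(c(e_l, e_w, e_fd), "percentage errors", strict = FALSE)
  ed <- (e_l + e_w + e_fd) / 3
  if (literal) ed * 100 else ed
}

#' Manual (caliper-based) similarity
#'
#' \eqn{Similarity = 100\% - E_D}, floored at 0.
#'
#' @param e_d normalized error in percent (>= 0).
#' @return Similarity, percent in \[0, 100\].
#' @export
manual_similarity <- function(e_d) {
  check_positive(e_d, "e_d", strict = FALSE)
  clamp_pct(100 - e_d)
}

#' Score one print against its CAD target
#'
#' End-to-end fidelity scoring: preprocess the photograph, compare it to a
#' reference render of the CAD design (SSIM), compare measured dimensions
#' to the CAD dimensions (dimensional similarity, percentage errors), and
#' combine into the aggregate and manual similarity scores.
#'
#' @param image a [print_image()] photograph of the printed mesh.
#' @param cad a [cad_spec()].
#' @param reference optional reference [print_image()] of the CAD design
#'   at the same physical scale; if `NULL` an ideal mesh is rendered via
#'   [render_mesh()] at the image's scale and size.
#' @param measured optional [mesh_measurement()] (caliper values); if
#'   `NULL`, measured from the preprocessed image via [measure_mesh()].
#' @param target_size preprocessing size, default `c(128, 128)`.
#' @param gaussian_sigma preprocessing smoothing, default 1 px.
#' @return An object of class `fidelity_scores`: list with `ssim`
#'   (\[-1,1\]), `ssim_pct`, `sd`, `sa`, `manual_similarity`, `errors`
#'   (`e_l`, `e_w`, `e_fd`, `e_d`) and the `measured` dimensions used.
#' @export
score_print <- function(image, cad, reference = NULL, measured = NULL,
                        target_size = c(128, 128), gaussian_sigma = 1) {
  stopifnot(inherits(image, "print_image"), inherits(cad, "cad_spec"))
  pre <- preprocess_image(image, target_size, gaussian_sigma)
  if (is.null(reference)) {
    spec <- mesh_render_spec(cad = cad,
                             image_size = dim(image$pixels)[1],
                             mm_per_pixel = image$mm_per_pixel)
    reference <- render_mesh(spec)$image
  }
  ref_pre <- preprocess_image(reference, target_size, gaussian_sigma)
  s <- ssim(pre, ref_pre)
  s_pct <- clamp_pct(100 * s)
  if (is.null(measured)) {
    # measure at the native resolution: the downsampled image is for
    # structural comparison, too coarse for strand-width calipering
    native <- preprocess_image(image, target_size = dim(image$pixels),
                               gaussian_sigma = gaussian_sigma)
    measured <- measure_mesh(native)
  }
  sd_pct <- dimensional_similarity(measured, cad)
  sa <- aggregate_similarity(s_pct, sd_pct)
  errs <- percent_errors(measured, cad)
  ed <- normalized_error(errs["e_l"], errs["e_w"], errs["e_fd"])
  man <- manual_similarity(ed)
  structure(
    list(ssim = s, ssim_pct = s_pct, sd = sd_pct, sa = clamp_pct(sa),
         manual_similarity = man,
         errors = c(errs, e_d = unname(ed)),
         measured = measured),
    class = "fidelity_scores"
  )
}

#' @export
print.fidelity_scores <- function(x, ...) {
  cat("<fidelity_scores>\n")
  cat(sprintf("  SSIM = %.4f (%.2f%%), SD = %.2f%%, SA = %.2f%%\n",
              x$ssim, x$ssim_pct, x$sd, x$sa))
  cat(sprintf("  errors: E_L = %.2f%%, E_W = %.2f%%, E_FD = %.2f%%, E_D = %.2f%%\n",
              x$errors["e_l"], x$errors["e_w"], x$errors["e_fd"], x$errors["e_d"]))
  cat(sprintf("  manual similarity = %.2f%%\n", x$manual_similarity))
  invisible(x)
}
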