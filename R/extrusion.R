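# Analytic 1-D power-law extrusion model for a cylindrical nozzle channel.
#
# The model chain: volumetric flow from extrusion velocity and bore area;
# centerline (maximum) velocity from the power-law profile factor; the
# generalized Hagen-Poiseuille relation linking pressure drop, consistency
# index and velocity; and the deposited filament diameter from the
# velocity ratio. Two printed-formula quirks are handled explicitly, see
# `profile` below and the package vignette.

#' Volumetric flow rate through the nozzle
#'
#' Flow is the product of extrusion velocity and the bore cross-sectional
#' area: \eqn{Q = V_{EXT} \pi R^2}.
#'
#' @param v_ext extrusion velocity, mm/s (>= 0).
#' @param nozzle a [nozzle_geometry()].
#' @return Flow rate in mm^3/s.
#' @examples
#' flow_rate(25, nozzle_geometry(25)) # ~1.227 mm^3/s
#' @export
flow_rate <- function(v_ext, nozzle) {
  check_positive(v_ext, "v_ext", strict = FALSE)
  stopifnot(inherits(nozzle, "nozzle_geometry"))
  v_ext * pi * nozzle$radius^2
}

#' Maximum (centerline) velocity of power-law channel flow
#'
#' Relates the mean extrusion velocity to the channel's peak velocity via
#' the flow-behavior index. The default `profile = "astrid"` uses the
#' factor \eqn{(3n+1)/n} as stated by the source model;
#' `profile = "textbook"` uses the classical fully developed power-law
#' pipe-flow ratio \eqn{(3n+1)/(n+1)}. The two coincide nowhere except in
#' the limit; both are provided so predictions can be compared.
#'
#' @param v_ext extrusion velocity, mm/s (>= 0).
#' @param n flow-behavior index (> 0).
#' @param profile `"astrid"` (default) or `"textbook"`.
#' @return Maximum velocity in mm/s.
#' @examples
#' max_velocity(10, 1)   # 40 (astrid factor at n = 1)
#' max_velocity(10, 1, profile = "textbook") # 20, the parabolic limit
#' @export
max_velocity <- function(v_ext, n, profile = c("astrid", "textbook")) {
  profile <- match.arg(profile)
  check_positive(v_ext, "v_ext", strict = FALSE)
  check_positive(n, "n")
  fac <- switch(profile,
    astrid = (3 * n + 1) / n,
    textbook = (3 * n + 1) / (n + 1)
  )
  v_ext * fac
}

#' Pressure drop along the nozzle channel (Hagen-Poiseuille)
#'
#' \eqn{\Delta P = 8 \eta V_{EXT} L / R^2}, in SI units.
#'
#' @param eta effective dynamic viscosity, Pa·s (> 0).
#' @param v_ext extrusion velocity, m/s (> 0).
#' @param L channel length, m (> 0).
#' @param R channel radius, m (> 0).
#' @return Pressure drop in Pa.
#' @examples
#' pressure_drop(2.88, 0.025, 0.01, 1.25e-4) # 368640 Pa
#' @export
pressure_drop <- function(eta, v_ext, L, R) {
  check_positive(eta, "eta")
  check_positive(v_ext, "v_ext")
  check_positive(L, "L")
  check_positive(R, "R")
  8 * eta * v_ext * L / R^2
}

#' Extrusion velocity from pressure for a power-law fluid
#'
#' Generalized Hagen-Poiseuille relation solved for velocity:
#' \deqn{V_{EXT} = \frac{n}{3n+1} \frac{R^2}{K} \frac{\Delta P}{L}}
#' Exact algebraic inverse of [consistency_index()].
#'
#' @param n flow-behavior index (> 0).
#' @param K consistency index, Pa·s^n (> 0).
#' @param R channel radius (> 0).
#' @param dP pressure drop (> 0).
#' @param L channel length (> 0).
#' @return Extrusion velocity (units follow the inputs; SI in = SI out).
#' @export
extrusion_velocity_from_pressure <- function(n, K, R, dP, L) {
  check_positive(n, "n"); check_positive(K, "K"); check_positive(R, "R")
  check_positive(dP, "dP"); check_positive(L, "L")
  n / (3 * n + 1) * R^2 / K * dP / L
}

#' Consistency index from an observed extrusion velocity
#'
#' \deqn{K = \frac{n}{3n+1} \frac{R^2}{V_{EXT}} \frac{\Delta P}{L}}
#' Exact algebraic inverse of [extrusion_velocity_from_pressure()].
#'
#' @inheritParams extrusion_velocity_from_pressure
#' @param v_ext extrusion velocity (> 0).
#' @return Consistency index K.
#' @export
consistency_index <- function(n, R, v_ext, dP, L) {
  check_positive(n, "n"); check_positive(R, "R"); check_positive(v_ext, "v_ext")
  check_positive(dP, "dP"); check_positive(L, "L")
  n / (3 * n + 1) * R^2 / v_ext * dP / L
}

#' Predicted deposited filament diameter
#'
#' \deqn{D_F = \frac{4 \, W_N \, V_{EXT}}{n \, V_{MAX}}}
#' with `W_N` the nozzle inner *diameter* (the only dimensionally
#' consistent reading). When `v_max` comes from [max_velocity()] with the
#' default profile this reduces to \eqn{D_F = 4 W_N / (3n + 1)}: at n = 1
#' the filament equals the bore, and for shear-thinning inks (n < 1) the
#' predicted strand is wider than the bore (die swell).
#'
#' @param nozzle a [nozzle_geometry()].
#' @param v_ext extrusion velocity, mm/s (> 0).
#' @param n flow-behavior index (> 0).
#' @param v_max maximum velocity, mm/s (> 0); typically [max_velocity()].
#' @return Filament diameter in mm.
#' @examples
#' nz <- nozzle_geometry(25)
#' filament_diameter(nz, 25, 1, max_velocity(25, 1)) # = 0.250, the bore
#' @export
filament_diameter <- function(nozzle, v_ext, n, v_max) {
  stopifnot(inherits(nozzle, "nozzle_geometry"))
  check_positive(v_ext, "v_ext")
  check_positive(n, "n")
  check_positive(v_max, "v_max")
  4 * nozzle$inner_diameter * v_ext / (n * v_max)
}

#' Full extrusion report for one process setting
#'
#' Chains the analytic model: fits (or accepts) power-law parameters,
#' computes flow rate, maximum velocity, effective viscosity, pressure
#' drop and predicted filament diameter for a nozzle/pressure/velocity
#' setting.
#'
#' The effective dynamic viscosity defaults to the apparent power-law
#' viscosity at the characteristic shear rate `v_ext / R` unless supplied.
#'
#' @param rheology a [rheology_curve()] or a [power_law_fit()].
#' @param nozzle a [nozzle_geometry()].
#' @param velocity extrusion velocity, mm/s.
#' @param pressure applied pressure, kPa (reported back; the model's
#'   pressure drop is computed from viscosity, not from this input).
#' @param temperature process temperature, degrees C (metadata).
#' @param eta optional effective dynamic viscosity, Pa·s.
#' @param window optional fit window passed to [fit_power_law()].
#' @param profile velocity-profile factor, see [max_velocity()].
#' @return An object of class `extrusion_report`: list with `n`, `K`,
#'   `r_squared`, `flow_rate_mm3_s`, `v_max_mm_s`, `eta_Pa_s`,
#'   `pressure_drop_kPa`, `filament_diameter_mm`, plus the inputs and
#'   `channel_length_default` flag.
#' @export
extrusion_report <- function(rheology, nozzle, velocity, pressure = NA_real_,
                             temperature = NA_real_, eta = NULL,
                             window = NULL, profile = "astrid") {
  fit <- if (inherits(rheology, "power_law_fit")) rheology
         else fit_power_law(rheology, window = window)
  check_positive(velocity, "velocity")
  q <- flow_rate(velocity, nozzle)
  vmax <- max_velocity(velocity, fit$n, profile = profile)
  if (is.null(eta)) {
    eta <- apparent_viscosity(fit, velocity / nozzle$radius)
  }
  dp <- pressure_drop(eta, mm_to_m(velocity), mm_to_m(nozzle$channel_length),
                      mm_to_m(nozzle$radius))
  df <- filament_diameter(nozzle, velocity, fit$n, vmax)
  structure(
    list(
      n = fit$n, K = fit$K, r_squared = fit$r_squared,
      flow_rate_mm3_s = q, v_max_mm_s = vmax, eta_Pa_s = eta,
      pressure_drop_kPa = pa_to_kpa(dp), filament_diameter_mm = df,
      velocity_mm_s = velocity, applied_pressure_kPa = pressure,
      temperature_C = temperature,
      nozzle = nozzle,
      channel_length_default = isTRUE(nozzle$channel_length_default),
      profile = profile
    ),
    class = "extrusion_report"
  )
}

#' @export
print.extrusion_report <- function(x, ...) {
  cat("<extrusion_report>\n")
  cat(sprintf("  ink: n = %.4f, K = %.4g Pa.s^n (R^2 = %.3f)\n", x$n, x$K, x$r_squared))
  cat(sprintf("  nozzle: %s bore %.3f mm, channel %.1f mm%s\n",
              if (is.na(x$nozzle$gauge)) "custom" else paste0(x$nozzle$gauge, "G"),
              x$nozzle$inner_diameter, x$nozzle$channel_length,
              if (x$channel_length_default) " [default]" else ""))
  cat(sprintf("  Q = %.4g mm^3/s, V_max = %.4g mm/s, eta_eff = %.4g Pa.s\n",
              x$flow_rate_mm3_s, x$v_max_mm_s, x$eta_Pa_s))
  cat(sprintf("  dP = %.4g kPa, predicted filament diameter = %.4f mm\n",
              x$pressure_drop_kPa, x$filament_diameter_mm))
  invisible(x)
}
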