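#' Rheology flow curve
#'
#' Container for a measured flow curve: apparent viscosity (and optionally
#' shear stress) as a function of shear rate, at a fixed temperature.
#' Shear-thinning inks show viscosity decreasing with shear rate; the
#' power-law model \eqn{\eta = K \dot\gamma^{n-1}} is fitted to this curve
#' by [fit_power_law()].
#'
#' @param shear_rate strictly increasing shear rates, 1/s (length >= 3).
#' @param viscosity apparent viscosities, Pa·s (strictly positive, same
#'   length as `shear_rate`).
#' @param shear_stress optional shear stresses, Pa.
#' @param temperature measurement temperature, degrees C (metadata).
#' @return An object of class `rheology_curve`.
#' @examples
#' rheology_curve(c(1, 10, 100), 120 * c(1, 10, 100)^(-0.6))
#' @export
rheology_curve <- function(shear_rate, viscosity, shear_stress = NULL,
                           temperature = NA_real_) {
  check_positive(shear_rate, "shear_rate")
  check_positive(viscosity, "viscosity")
  if (length(shear_rate) != length(viscosity)) {
    stop_domain("shear_rate and viscosity must have equal length")
  }
  if (length(shear_rate) < 3) {
    stop_domain("a flow curve needs at least 3 points")
  }
  if (any(diff(shear_rate) <= 0)) {
    stop_domain("shear_rate must be strictly increasing")
  }
  if (!is.null(shear_stress) && length(shear_stress) != length(shear_rate)) {
    stop_domain("shear_stress must match shear_rate in length")
  }
  structure(
    list(shear_rate = as.numeric(shear_rate),
         viscosity = as.numeric(viscosity),
         shear_stress = shear_stress,
         temperature = temperature),
    class = "rheology_curve"
  )
}

#' @export
print.rheology_curve <- function(x, ...) {
  cat(sprintf("<rheology_curve> %d points, shear rate %.3g-%.3g 1/s, viscosity %.3g-%.3g Pa.s%s\n",
              length(x$shear_rate), min(x$shear_rate), max(x$shear_rate),
              min(x$viscosity), max(x$viscosity),
              if (is.na(x$temperature)) "" else sprintf(", %g degC", x$temperature)))
  invisible(x)
}

#' Read a rheology flow curve from CSV
#'
#' Expects header columns `shear_rate_1_per_s`, `viscosity_Pa_s`, optional
#' `shear_stress_Pa` and `temperature_C`.
#'
#' @param path CSV file path.
#' @return A [rheology_curve()].
#' @export
read_rheology_csv <- function(path) {
  d <- read.csv(path)
  need <- c("shear_rate_1_per_s", "viscosity_Pa_s")
  if (!all(need %in% names(d))) {
    stop_domain("rheology CSV must have columns %s", paste(need, collapse = ", "))
  }
  rheology_curve(
    shear_rate = d$shear_rate_1_per_s,
    viscosity = d$viscosity_Pa_s,
    shear_stress = if ("shear_stress_Pa" %in% names(d)) d$shear_stress_Pa else NULL,
    temperature = if ("temperature_C" %in% names(d)) d$temperature_C[1] else NA_real_
  )
}

#' Fit the power-law (Ostwald-de Waele) viscosity model
#'
#' Ordinary least squares in log-log space:
#' \deqn{\log \eta = \log K + (n - 1) \log \dot\gamma}
#' yielding the flow-behavior index `n` (n < 1 indicates shear thinning)
#' and the consistency index `K` (Pa·s^n). The fit window defaults to the
#' full curve.
#'
#' @param curve a [rheology_curve()].
#' @param window optional shear-rate pair `c(lo, hi)` restricting the fit
#'   (inclusive); at least 3 points must fall inside.
#' @return An object of class `power_law_fit`: list with `n`, `K`,
#'   `r_squared` and `shear_rate_window`.
#' @examples
#' cv <- rheology_curve(c(1, 5, 10, 20), rep(2, 4))
#' fit_power_law(cv) # Newtonian: n = 1, K = 2
#' @export
fit_power_law <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "rheology_curve"))
  rate <- curve$shear_rate
  eta <- curve$viscosity
  if (is.null(window)) {
    window <- range(rate)
  }
  if (length(window) != 2 || window[1] >= window[2]) {
    stop_domain("`window` must be an increasing shear-rate pair")
  }
  keep <- rate >= window[1] & rate <= window[2]
  if (sum(keep) < 3) {
    stop_domain("fewer than 3 points inside the fit window [%g, %g]",
                window[1], window[2])
  }
  lx <- log(rate[keep])
  ly <- log(eta[keep])
  fit <- lm(ly ~ lx)
  n <- unname(coef(fit)[2]) + 1
  K <- exp(unname(coef(fit)[1]))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(
    list(n = n, K = K, r_squared = r2, shear_rate_window = window),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> n = %.4f (%s), K = %.4g Pa.s^n, R^2 = %.4f, window [%g, %g] 1/s\n",
              x$n, if (x$n < 1) "shear thinning" else if (x$n > 1) "shear thickening" else "Newtonian",
              x$K, x$r_squared, x$shear_rate_window[1], x$shear_rate_window[2]))
  invisible(x)
}

#' Apparent power-law viscosity at a shear rate
#'
#' \eqn{\eta(\dot\gamma) = K \dot\gamma^{n-1}}.
#'
#' @param fit a [power_law_fit()] or list with `n` and `K`.
#' @param shear_rate shear rate(s), 1/s (> 0).
#' @return Viscosity in Pa·s.
#' @export
apparent_viscosity <- function(fit, shear_rate) {
  check_positive(shear_rate, "shear_rate")
  fit$K * shear_rate^(fit$n - 1)
}
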