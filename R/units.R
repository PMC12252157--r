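# Central unit conversions. Public API speaks printer-native units
# (mm, mm/s, kPa); the generalized Hagen-Poiseuille relation is evaluated
# in SI and converted back here.

#' Unit conversion helpers
#'
#' The package's public interface uses printer-native units: lengths in mm,
#' velocities in mm/s, pressures in kPa, viscosities in Pa·s. All
#' conversions to and from SI are centralized in these helpers.
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @keywords internal
#' @name units
NULL

#' @rdname units
mm_to_m <- function(x) x / 1000

#' @rdname units
m_to_mm <- function(x) x * 1000

#' @rdname units
kpa_to_pa <- function(x) x * 1000

#' @rdname units
pa_to_kpa <- function(x) x / 1000

# shared argument checking ---------------------------------------------------

stop_domain <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_domain("`%s` must be numeric and non-missing", name)
  }
  if (strict && any(x <= 0)) {
    stop_domain("`%s` must be strictly positive (got %s)", name,
                paste(signif(x[x <= 0], 4), collapse = ", "))
  }
  if (!strict && any(x < 0)) {
    stop_domain("`%s` must be non-negative (got %s)", name,
                paste(signif(x[x < 0], 4), collapse = ", "))
  }
  invisible(x)
}
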