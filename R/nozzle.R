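#' Needle gauge to inner diameter lookup (mm)
#'
#' Conical bioprinting tips are specified by needle gauge; the extrusion
#' model needs the bore. The shipped table covers the two gauges used on
#' the BIO X-class printers this package targets: 25G = 0.250 mm and
#' 27G = 0.210 mm. Override or extend via the `table` argument of
#' [nozzle_geometry()].
#'
#' @format Named numeric vector, names are gauge numbers, values inner
#'   diameters in mm.
#' @export
gauge_table <- c("25" = 0.250, "27" = 0.210)

#' Nozzle geometry
#'
#' Describes the extrusion nozzle: gauge, inner diameter (the bore width
#' used by the filament-diameter relation), radius, and channel length.
#'
#' @param gauge integer needle gauge (e.g. 25 or 27), or `NULL` if
#'   `inner_diameter` is given directly.
#' @param inner_diameter bore diameter in mm; defaults to the gauge lookup.
#' @param channel_length length of the nozzle channel in mm. Not printed on
#'   standard tips; defaults to 12.7 mm (a standard half-inch tip) and is
#'   flagged as a default in reports.
#' @param table gauge lookup table (named numeric vector, mm); defaults to
#'   [gauge_table].
#' @return An object of class `nozzle_geometry`: list with `gauge`,
#'   `inner_diameter` (mm), `radius` (mm, exactly `inner_diameter / 2`),
#'   `channel_length` (mm) and `channel_length_default` (logical).
#' @examples
#' nozzle_geometry(25)
#' nozzle_geometry(inner_diameter = 0.41) # 22G, user-supplied bore
#' @export
nozzle_geometry <- function(gauge = NULL, inner_diameter = NULL,
                            channel_length = 12.7, table = gauge_table) {
  if (is.null(inner_diameter)) {
    if (is.null(gauge)) {
      stop_domain("supply either `gauge` or `inner_diameter`")
    }
    key <- as.character(gauge)
    if (!key %in% names(table)) {
      stop_domain("gauge %sG not in lookup table (known: %s); pass `inner_diameter`",
                  key, paste(names(table), collapse = ", "))
    }
    inner_diameter <- unname(table[key])
  }
  check_positive(inner_diameter, "inner_diameter")
  check_positive(channel_length, "channel_length")
  structure(
    list(
      gauge = if (is.null(gauge)) NA_integer_ else as.integer(gauge),
      inner_diameter = inner_diameter,
      radius = inner_diameter / 2,
      channel_length = channel_length,
      channel_length_default = missing(channel_length)
    ),
    class = "nozzle_geometry"
  )
}

#' @export
print.nozzle_geometry <- function(x, ...) {
  cat(sprintf("<nozzle_geometry> %s bore %.3f mm (radius %.4f mm), channel %.1f mm%s\n",
              if (is.na(x$gauge)) "custom" else paste0(x$gauge, "G"),
              x$inner_diameter, x$radius, x$channel_length,
              if (isTRUE(x$channel_length_default)) " [default]" else ""))
  invisible(x)
}
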