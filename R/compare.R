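#' Report for one parameter-estimation method
#'
#' One row of the three-way comparison between estimation methods
#' (experimental measurement, the analytic extrusion model, and the
#' image classifier): the selected printing parameters, the resulting
#' filament diameter and similarity, and the method's agreement
#' statistics.
#'
#' @param method method label, e.g. `"experimental"`, `"analytic_model"`,
#'   `"ml_model"`.
#' @param nozzle_G nozzle gauge.
#' @param pressure_kPa applied pressure, kPa (must be <= 200, the
#'   printer's ceiling).
#' @param velocity_mm_s printing velocity, mm/s (<= 45).
#' @param temperature_C process temperature, degrees C.
#' @param filament_diameter_mm resulting filament diameter, mm.
#' @param similarity_pct similarity to CAD, percent.
#' @param mae,mse,r agreement statistics versus the reference
#'   measurements (may be `NA` when not applicable).
#' @return An object of class `run_report`.
#' @export
run_report <- function(method, nozzle_G, pressure_kPa, velocity_mm_s,
                       temperature_C = 32, filament_diameter_mm = NA_real_,
                       similarity_pct = NA_real_, mae = NA_real_,
                       mse = NA_real_, r = NA_real_) {
  if (!is.na(pressure_kPa) && (pressure_kPa <= 0 || pressure_kPa > 200)) {
    stop_domain("pressure %g kPa outside the printer range (0, 200]", pressure_kPa)
  }
  if (!is.na(velocity_mm_s) && (velocity_mm_s <= 0 || velocity_mm_s > 45)) {
    stop_domain("velocity %g mm/s outside the printer range (0, 45]", velocity_mm_s)
  }
  structure(
    list(method = method, nozzle_G = nozzle_G, pressure_kPa = pressure_kPa,
         velocity_mm_s = velocity_mm_s, temperature_C = temperature_C,
         filament_diameter_mm = filament_diameter_mm,
         similarity_pct = similarity_pct, mae = mae, mse = mse, r = r),
    class = "run_report"
  )
}

#' Compare parameter-estimation methods
#'
#' Assembles run reports into one comparison table (one row per method:
#' parameters, filament diameter, similarity, MAE, MSE, Pearson r) and
#' flags the best method by lowest MAE. Missing metrics are emitted as
#' `NA`, never dropped.
#'
#' @param reports list of [run_report()]s (>= 2, distinct method names).
#' @return A `data.frame` of class `method_comparison` with attribute
#'   `best_method`.
#' @export
compare_methods <- function(reports) {
  if (length(reports) < 2) stop_domain("need at least 2 reports to compare")
  stopifnot(all(vapply(reports, inherits, logical(1), "run_report")))
  methods <- vapply(reports, `[[`, character(1), "method")
  if (anyDuplicated(methods)) {
    stop_domain("duplicate method names: %s",
                paste(unique(methods[duplicated(methods)]), collapse = ", "))
  }
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(method = r$method, nozzle_G = r$nozzle_G,
               pressure_kPa = r$pressure_kPa, velocity_mm_s = r$velocity_mm_s,
               temperature_C = r$temperature_C,
               filament_diameter_mm = r$filament_diameter_mm,
               similarity_pct = r$similarity_pct,
               mae = r$mae, mse = r$mse, r = r$r)
  }))
  rownames(tab) <- NULL
  best <- if (all(is.na(tab$mae))) NA_character_ else {
    tab$method[which.min(tab$mae)]
  }
  attr(tab, "best_method") <- best
  class(tab) <- c("method_comparison", "data.frame")
  tab
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print.data.frame(x)
  cat(sprintf("best method (lowest MAE): %s\n", attr(x, "best_method")))
  invisible(x)
}

#' Write a comparison table to CSV or JSON
#'
#' @param comparison a [compare_methods()] table.
#' @param path output file; format chosen by extension (.csv or .json).
#' @export
write_comparison <- function(comparison, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(comparison = comparison, best_method = attr(comparison, "best_method")),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    write.csv(comparison, path, row.names = FALSE)
  }
  invisible(path)
}
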