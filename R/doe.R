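# Full-factorial design-of-experiments machinery on the printer's three
# process factors, with the centered coding used throughout:
#   A = nozzle gauge  (centered A - 26; 27G -> +1, 25G -> -1)
#   B = pressure, kPa (centered B - 180)
#   C = velocity, mm/s (centered C - 15)
# Polynomial models are linear in the centered monomials
# {A, B, C, AB, AC, BC, ABC}; coefficients are therefore directly
# comparable across fitted and literal reference models.

doe_levels <- list(
  nozzle_G = c(27, 25),
  pressure_kPa = c(160, 170, 180, 190, 200),
  velocity_mm_s = c(5, 10, 15, 20, 25)
)
doe_centers <- c(A = 26, B = 180, C = 15)
doe_terms <- c("A", "B", "C", "AB", "AC", "BC", "ABC")

centered_monomials <- function(A, B, C, terms = doe_terms) {
  a <- unname(A - doe_centers[["A"]])
  b <- unname(B - doe_centers[["B"]])
  cc <- unname(C - doe_centers[["C"]])
  cols <- list(A = a, B = b, C = cc, AB = a * b, AC = a * cc,
               BC = b * cc, ABC = a * b * cc)
  m <- do.call(cbind, cols[terms])
  colnames(m) <- terms
  m
}

#' Build the full factorial design
#'
#' The 2 x 5 x 5 crossing of nozzle gauge (27, 25 G), applied pressure
#' (160-200 kPa in 10 kPa steps) and printing velocity (5-25 mm/s in
#' 5 mm/s steps): 50 distinct cells, each repeated `replicates` times, in
#' deterministic order (velocity fastest, nozzle slowest).
#'
#' @param replicates runs per cell (>= 1). 17 replicates gives the
#'   850-run scale used for classifier training data.
#' @return A `data.frame` of class `factorial_design` with columns
#'   `run_id`, `nozzle_G`, `pressure_kPa`, `velocity_mm_s` and the
#'   centered codes `A_c`, `B_c`, `C_c`.
#' @examples
#' nrow(full_factorial_design())   # 50
#' nrow(full_factorial_design(17)) # 850
#' @export
full_factorial_design <- function(replicates = 1) {
  if (!is.numeric(replicates) || replicates < 1 || replicates %% 1 != 0) {
    stop_domain("`replicates` must be a positive integer")
  }
  cells <- expand.grid(
    velocity_mm_s = doe_levels$velocity_mm_s,
    pressure_kPa = doe_levels$pressure_kPa,
    nozzle_G = doe_levels$nozzle_G,
    KEEP.OUT.ATTRS = FALSE
  )[, c("nozzle_G", "pressure_kPa", "velocity_mm_s")]
  d <- cells[rep(seq_len(nrow(cells)), times = replicates), , drop = FALSE]
  d <- d[order(rep(seq_len(nrow(cells)), times = replicates)), , drop = FALSE]
  rownames(d) <- NULL
  d <- cbind(run_id = seq_len(nrow(d)), d)
  d$A_c <- d$nozzle_G - doe_centers["A"]
  d$B_c <- d$pressure_kPa - doe_centers["B"]
  d$C_c <- d$velocity_mm_s - doe_centers["C"]
  class(d) <- c("factorial_design", "data.frame")
  d
}

check_design_cells <- function(runs) {
  cells <- expand.grid(nozzle_G = doe_levels$nozzle_G,
                       pressure_kPa = doe_levels$pressure_kPa,
                       velocity_mm_s = doe_levels$velocity_mm_s)
  have <- paste(runs$nozzle_G, runs$pressure_kPa, runs$velocity_mm_s)
  want <- paste(cells$nozzle_G, cells$pressure_kPa, cells$velocity_mm_s)
  missing <- setdiff(want, unique(have))
  if (length(missing) > 0) {
    stop_domain("design has empty cells (A pressure velocity): %s",
                paste(head(missing, 5), collapse = "; "))
  }
  invisible(TRUE)
}

# p-values for a fitted model; in the exact-fit regime (residual sigma at
# rounding-error level) t-statistics are ratios of rounding errors, so
# terms are classified by coefficient magnitude instead.
term_p_values <- function(fit, y) {
  sm <- suppressWarnings(summary(fit))
  sigma <- sm$sigma
  co <- coef(fit)
  scale_y <- max(sd(y), 1e-12)
  if (is.finite(sigma) && sigma < 1e-10 * scale_y) {
    p <- ifelse(abs(co) > 1e-8 * max(1, scale_y), 0, 1)
  } else {
    p <- sm$coefficients[, "Pr(>|t|)"]
  }
  names(p) <- names(co)
  p
}

#' Fit the centered-coded polynomial factorial model
#'
#' Ordinary least squares of a response on the centered monomials
#' `{A, B, C, AB, AC, BC, ABC}` (plus intercept), with per-term t-test
#' p-values and R-squared. Backed by [stats::lm()].
#'
#' @param runs data.frame with columns `nozzle_G`, `pressure_kPa`,
#'   `velocity_mm_s` and the response; every design cell must be present.
#' @param response_name name of the response column.
#' @param terms monomials to include (default all seven).
#' @return An object of class `factorial_model`: coefficients, `p_values`,
#'   `r_squared`, residual `sigma`, `df_residual`, the term set, and the
#'   data for refitting.
#' @export
fit_factorial_model <- function(runs, response_name, terms = doe_terms) {
  if (!response_name %in% names(runs)) {
    stop_domain("response `%s` not found in runs", response_name)
  }
  check_design_cells(runs)
  y <- runs[[response_name]]
  if (anyNA(y) || any(!is.finite(y))) stop_domain("response contains non-finite values")
  terms <- match.arg(terms, doe_terms, several.ok = TRUE)
  X <- centered_monomials(runs$nozzle_G, runs$pressure_kPa, runs$velocity_mm_s, terms)
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  sm <- suppressWarnings(summary(fit))
  r2 <- if (sd(y) == 0) 0 else sm$r.squared
  co <- coef(fit)
  names(co)[1] <- "(Intercept)"
  structure(
    list(response_name = response_name,
         terms = terms,
         coefficients = co,
         p_values = term_p_values(fit, y),
         r_squared = r2,
         sigma = sm$sigma,
         df_residual = fit$df.residual,
         source = "fitted",
         data = runs,
         prune_trace = NULL),
    class = "factorial_model"
  )
}

#' Prune non-significant terms and refit
#'
#' Single-pass pruning at level `alpha`: every non-intercept term with
#' p >= alpha is removed, then the model is refitted on the surviving
#' terms. No hierarchical protection is applied (reference surfaces in
#' the field drop main effects while keeping interactions). The pruning
#' trace (term, p, kept) is attached to the result.
#'
#' @param model a fitted [fit_factorial_model()] result.
#' @param alpha significance level, default 0.01.
#' @return A refitted `factorial_model` with `prune_trace`.
#' @export
prune_model <- function(model, alpha = 0.01) {
  stopifnot(inherits(model, "factorial_model"))
  if (identical(model$source, "reference")) {
    stop_domain("reference models carry no p-values to prune")
  }
  p <- model$p_values[model$terms]
  keep <- p < alpha
  trace <- data.frame(term = model$terms, p_value = unname(p),
                      kept = unname(keep))
  surviving <- model$terms[keep]
  out <- if (length(surviving) == 0) {
    y <- model$data[[model$response_name]]
    structure(
      list(response_name = model$response_name, terms = character(0),
           coefficients = c("(Intercept)" = mean(y)),
           p_values = c("(Intercept)" = 0),
           r_squared = 0, sigma = sd(y), df_residual = length(y) - 1,
           source = "fitted", data = model$data, prune_trace = NULL),
      class = "factorial_model")
  } else {
    fit_factorial_model(model$data, model$response_name, terms = surviving)
  }
  out$prune_trace <- trace
  out
}

#' Literal reference response surfaces
#'
#' The two published centered-coded regression surfaces shipped as named
#' models, independent of any fitting: `"eq19"` predicts filament
#' diameter (mm) and `"eq20"` predicts SSIM similarity (percent), both on
#' the centered factors (A - 26, B - 180, C - 15) with retained terms
#' `{A, B, C, AB, AC}`. Their reported fit qualities (R-squared 0.85 and
#' 0.97) are carried as metadata. They serve as reference oracles for the
#' fitting machinery and as truth surfaces for the synthetic generator.
#'
#' @param name `"eq19"` or `"eq20"`.
#' @return A `factorial_model` with `source = "reference"`.
#' @examples
#' predict(reference_model("eq19"), A = 26, B = 180, C = 15) # 1.0980
#' @export
reference_model <- function(name = c("eq19", "eq20")) {
  name <- match.arg(name)
  co <- switch(name,
    eq19 = c("(Intercept)" = 1.0980, A = -0.5492, B = 0.0073,
             C = -0.0648, AB = -0.0088, AC = -0.0403),
    eq20 = c("(Intercept)" = 51.810, A = 0.233, B = 0.10,
             C = 0.02, AB = 0.28, AC = -0.63)
  )
  structure(
    list(response_name = switch(name, eq19 = "filament_diameter_mm",
                                eq20 = "ssim_pct"),
         terms = c("A", "B", "C", "AB", "AC"),
         coefficients = co,
         p_values = setNames(rep(NA_real_, length(co)), names(co)),
         r_squared = switch(name, eq19 = 0.85, eq20 = 0.97),
         sigma = NA_real_, df_residual = NA_integer_,
         source = "reference", data = NULL, prune_trace = NULL),
    class = "factorial_model"
  )
}

#' Predict from a factorial model
#'
#' Evaluates intercept + sum of coefficient x centered monomial at the
#' supplied natural-unit factor settings (vectorized).
#'
#' @param object a `factorial_model`.
#' @param A nozzle gauge (e.g. 25 or 27).
#' @param B pressure, kPa.
#' @param C velocity, mm/s.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.factorial_model <- function(object, A, B, C, ...) {
  k <- max(length(A), length(B), length(C))
  A <- rep_len(A, k); B <- rep_len(B, k); C <- rep_len(C, k)
  out <- rep(object$coefficients[["(Intercept)"]], k)
  if (length(object$terms) > 0) {
    X <- centered_monomials(A, B, C, object$terms)
    out <- out + drop(X %*% object$coefficients[object$terms])
  }
  unname(out)
}

#' @export
print.factorial_model <- function(x, ...) {
  cat(sprintf("<factorial_model> %s ~ %s (%s)\n", x$response_name,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$source))
  co <- x$coefficients
  cat("  coefficients:\n")
  for (nm in names(co)) {
    pv <- x$p_values[nm]
    cat(sprintf("    %-12s %10.4f%s\n", nm, co[nm],
                if (is.na(pv)) "" else sprintf("  (p = %.3g)", pv)))
  }
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' Main-effect level means
#'
#' Mean response at every level of every factor. On a balanced design
#' these equal the balanced OLS effect predictions; on unbalanced data a
#' warning is raised and observation-weighted means are returned.
#'
#' @param runs data.frame with factor and response columns.
#' @param response_name response column name.
#' @return data.frame with columns `factor`, `level`, `mean`, `n`.
#' @export
main_effects <- function(runs, response_name) {
  if (!response_name %in% names(runs)) {
    stop_domain("response `%s` not found in runs", response_name)
  }
  y <- runs[[response_name]]
  out <- do.call(rbind, lapply(
    c("nozzle_G", "pressure_kPa", "velocity_mm_s"),
    function(f) {
      ag <- aggregate(y, by = list(level = runs[[f]]),
                      FUN = mean)
      cnt <- table(runs[[f]])
      data.frame(factor = f, level = ag$level, mean = ag$x,
                 n = as.integer(cnt[as.character(ag$level)]))
    }
  ))
  unbalanced <- any(vapply(c("nozzle_G", "pressure_kPa", "velocity_mm_s"),
                           function(f) length(unique(table(runs[[f]]))) > 1,
                           logical(1)))
  if (unbalanced) {
    warning("unbalanced design: level means are observation-weighted")
  }
  rownames(out) <- NULL
  out
}

#' Response-surface grid over two factors
#'
#' Dense prediction grid over a factor pair with the third factor fixed
#' (default: its design center).
#'
#' @param model a `factorial_model`.
#' @param factor_pair two of `"A"`, `"B"`, `"C"`.
#' @param fixed_level value for the remaining factor; default its center.
#' @param n grid points per axis (default 25).
#' @return data.frame with the two factor columns and `prediction`.
#' @export
response_surface_grid <- function(model, factor_pair = c("A", "B"),
                                  fixed_level = NULL, n = 25) {
  stopifnot(inherits(model, "factorial_model"))
  if (!all(factor_pair %in% c("A", "B", "C")) || length(factor_pair) != 2 ||
      factor_pair[1] == factor_pair[2]) {
    stop_domain("`factor_pair` must be two distinct of A, B, C")
  }
  ranges <- list(A = range(doe_levels$nozzle_G),
                 B = range(doe_levels$pressure_kPa),
                 C = range(doe_levels$velocity_mm_s))
  third <- setdiff(c("A", "B", "C"), factor_pair)
  if (is.null(fixed_level)) fixed_level <- unname(doe_centers[third])
  ax1 <- seq(ranges[[factor_pair[1]]][1], ranges[[factor_pair[1]]][2],
             length.out = n)
  ax2 <- seq(ranges[[factor_pair[2]]][1], ranges[[factor_pair[2]]][2],
             length.out = n)
  g <- expand.grid(x1 = ax1, x2 = ax2)
  vals <- list(A = NULL, B = NULL, C = NULL)
  vals[[factor_pair[1]]] <- g$x1
  vals[[factor_pair[2]]] <- g$x2
  vals[[third]] <- rep(fixed_level, nrow(g))
  out <- data.frame(g$x1, g$x2,
                    prediction = predict(model, A = vals$A, B = vals$B, C = vals$C))
  names(out)[1:2] <- factor_pair
  out
}

#' Comparison statistics: MAE, MSE, Pearson correlation
#'
#' Mean absolute error, mean squared error and the product-moment
#' correlation used to compare parameter-estimation methods.
#'
#' @param y,yhat observed and predicted vectors (equal length).
#' @param x,... see individual functions.
#' @return Scalar statistic.
#' @name comparison_stats
NULL

#' @rdname comparison_stats
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_domain("mae: unequal lengths")
  mean(abs(y - yhat))
}

#' @rdname comparison_stats
#' @export
mse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_domain("mse: unequal lengths")
  mean((y - yhat)^2)
}

#' @rdname comparison_stats
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_domain("pearson_r: unequal lengths")
  if (length(x) < 2) stop_domain("pearson_r needs at least 2 points")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_domain("pearson_r undefined for a constant vector")
  }
  cor(x, y)
}
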