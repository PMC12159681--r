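#' LMS z-score of a measurement
#'
#' Evaluates the Box-Cox style growth-model transform
#' `z = ((x/M)^L - 1) / (L * S)`, with the continuous limit
#' `z = log(x/M) / S` as L approaches 0. L is the skewness power, M the
#' median in parameter units and S the coefficient of variation.
#'
#' @param x measured value (> 0); vectorized.
#' @param L,M,S LMS parameters (M > 0, S > 0).
#' @return z-score(s).
#' @export
#' @examples
#' lms_z(14.39, L = 1.378, M = 36.715, S = 0.263)  # about -2
lms_z <- function(x, L, M, S) {
  stopifnot(is.numeric(x), is_num1(L), is_num1(M), is_num1(S))
  if (M <= 0 || S <= 0) stop_domain("M and S must be positive")
  if (any(!is.finite(x) | x <= 0)) stop_domain("measured values must be positive")
  if (abs(L) < 1e-7) log(x / M) / S else ((x / M)^L - 1) / (L * S)
}

#' Measurement value at a given z-score or centile of an LMS model
#'
#' Inverts the LMS transform: `x = M * (1 + L*S*z)^(1/L)` (or
#' `M * exp(S*z)` for L near 0). Either a z-score or a probability may be
#' supplied; probabilities are converted through the standard normal
#' quantile. Printed pediatric tables conventionally equate the 3rd and 97th
#' centiles with z = -2 and +2 (rather than the exact quantiles +/-1.8808);
#' `extreme_z2 = TRUE` (default) honors that convention for p = 0.03 / 0.97.
#'
#' @param z z-score(s); exactly one of `z`, `p` must be given.
#' @param p probability in (0, 1).
#' @param L,M,S LMS parameters.
#' @param extreme_z2 substitute z = +/-2 for p = 0.03 and 0.97.
#' @return measurement value(s) in parameter units.
#' @export
#' @examples
#' lms_centile(z = -2, L = 1.378, M = 36.715, S = 0.263)   # about 14.4
#' lms_centile(p = 0.25, L = 1.378, M = 36.715, S = 0.263) # about 30
lms_centile <- function(z = NULL, p = NULL, L, M, S, extreme_z2 = TRUE) {
  stopifnot(is_num1(L), is_num1(M), is_num1(S))
  if (M <= 0 || S <= 0) stop_domain("M and S must be positive")
  if (is.null(z) == is.null(p))
    stop_domain("supply exactly one of `z` or `p`")
  if (!is.null(p)) {
    stopifnot(all(p > 0 & p < 1))
    z <- stats::qnorm(p)
    if (extreme_z2) {
      z[abs(p - 0.03) < 1e-9] <- -2
      z[abs(p - 0.97) < 1e-9] <- 2
    }
  }
  if (abs(L) < 1e-7) return(M * exp(S * z))
  arg <- 1 + L * S * z
  if (any(arg <= 0))
    stop_domain(sprintf(
      "infeasible LMS inversion: 1 + L*S*z <= 0 (z = %g, L = %g, S = %g)",
      z[which(arg <= 0)[1]], L, S))
  M * arg^(1 / L)
}

#' Construct an LMS growth model
#'
#' @param grid data frame with columns `cov_value`, `L`, `M`, `S`, strictly
#'   increasing in `cov_value`, M > 0 and S > 0 throughout.
#' @param covariate one of `"age_years"`, `"height_cm"`, `"bsa_m2"`.
#' @param sex `"male"`, `"female"` or `"all"`.
#' @param parameter_id,units,citation,precision metadata carried into
#'   classification output.
#' @return an `lms_model` object.
#' @export
lms_model <- function(grid, covariate = c("age_years", "height_cm", "bsa_m2"),
                      sex = "all", parameter_id = NA_character_,
                      units = NA_character_, citation = NA_character_,
                      precision = 0L) {
  covariate <- match.arg(covariate)
  stopifnot(is.data.frame(grid),
            all(c("cov_value", "L", "M", "S") %in% names(grid)))
  grid <- grid[order(grid$cov_value), , drop = FALSE]
  if (any(diff(grid$cov_value) <= 0))
    stop_domain("LMS grid covariate values must be strictly increasing")
  if (any(grid$M <= 0) || any(grid$S <= 0))
    stop_domain("LMS grid requires M > 0 and S > 0 everywhere")
  structure(list(grid = grid, covariate = covariate, sex = sex,
                 parameter_id = parameter_id, units = units,
                 citation = citation, precision = precision),
            class = "lms_model")
}

#' @export
print.lms_model <- function(x, ...) {
  cat(sprintf("LMS model: %s (%s), %s, %s grid of %d rows [%g, %g]\n",
              x$parameter_id, x$units, x$sex, x$covariate, nrow(x$grid),
              min(x$grid$cov_value), max(x$grid$cov_value)))
  invisible(x)
}

#' Interpolate LMS parameters at a covariate value
#'
#' Component-wise linear interpolation between the bracketing grid rows;
#' exact at grid points. No extrapolation: growth models are invalid outside
#' the fitted range.
#'
#' @param model an [lms_model].
#' @param value covariate value (age, height or BSA per the model).
#' @return named list with `L`, `M`, `S`.
#' @export
lms_interpolate <- function(model, value) {
  stopifnot(inherits(model, "lms_model"), is_num1(value))
  g <- model$grid
  if (value < min(g$cov_value) || value > max(g$cov_value))
    stop_domain(sprintf("covariate %g outside the model grid [%g, %g]",
                        value, min(g$cov_value), max(g$cov_value)))
  list(L = stats::approx(g$cov_value, g$L, value)$y,
       M = stats::approx(g$cov_value, g$M, value)$y,
       S = stats::approx(g$cov_value, g$S, value)$y)
}

#' Construct a regression-based z-score model
#'
#' Pediatric vessel dimensions are commonly normalized through a fitted
#' allometric regression: `predicted = a + b * BSA^0.5` (or `a + b * BSA`),
#' with `z = (measured - predicted) / SD of residuals`.
#'
#' @param intercept,slope regression coefficients (predicted units).
#' @param transform `"sqrt_bsa"` or `"bsa"`.
#' @param sd_residuals residual SD (> 0), or `NA` when the source provides
#'   none (prediction only, no z-score).
#' @param parameter_id,site,units,citation metadata.
#' @return a `regression_z_model` object.
#' @export
regression_z_model <- function(intercept, slope,
                               transform = c("sqrt_bsa", "bsa"),
                               sd_residuals = NA_real_,
                               parameter_id = NA_character_,
                               site = NA_character_, units = NA_character_,
                               citation = NA_character_) {
  transform <- match.arg(transform)
  stopifnot(is_num1(intercept), is_num1(slope))
  if (!is.na(sd_residuals) && sd_residuals <= 0)
    stop_domain("sd_residuals must be positive when provided")
  structure(list(intercept = intercept, slope = slope, transform = transform,
                 sd_residuals = sd_residuals, parameter_id = parameter_id,
                 site = site, units = units, citation = citation),
            class = "regression_z_model")
}

#' @export
print.regression_z_model <- function(x, ...) {
  cat(sprintf("Regression z model: %s [%s], predicted = %g + %g * %s, residual SD %s\n",
              x$parameter_id, x$site, x$intercept, x$slope,
              if (x$transform == "sqrt_bsa") "BSA^0.5" else "BSA",
              if (is.na(x$sd_residuals)) "not available" else format(x$sd_residuals)))
  invisible(x)
}

#' Regression-based z-score
#'
#' @param measured measured value in model units.
#' @param bsa body surface area in m^2 (> 0).
#' @param model a [regression_z_model].
#' @return list with `predicted` and `z` (`z` is `NA` when the model carries
#'   no residual SD).
#' @export
#' @examples
#' m <- regression_z_model(0.57, 19.37, "sqrt_bsa", 2.38)
#' regression_z(19.94, bsa = 1, model = m)  # z = 0
regression_z <- function(measured, bsa, model) {
  stopifnot(inherits(model, "regression_z_model"), is_num1(measured))
  if (!is_num1(bsa) || bsa <= 0) stop_domain("`bsa` must be positive")
  pred <- model$intercept + model$slope *
    (if (model$transform == "sqrt_bsa") sqrt(bsa) else bsa)
  z <- if (is.na(model$sd_residuals)) NA_real_ else
    (measured - pred) / model$sd_residuals
  list(predicted = pred, z = z)
}

#' Construct a printed centile lookup table
#'
#' @param rows data frame with `cov_value` plus centile columns named
#'   `c<percent>` (e.g. `c05`, `c10`, ..., `c95`), monotone across centiles
#'   within each row and ordered by covariate.
#' @param covariate,sex,parameter_id,units,citation metadata.
#' @return a `centile_table` object.
#' @export
centile_table <- function(rows, covariate = c("height_cm", "bsa_m2", "age_years"),
                          sex = "all", parameter_id = NA_character_,
                          units = NA_character_, citation = NA_character_) {
  covariate <- match.arg(covariate)
  cc <- grep("^c[0-9]+$", names(rows), value = TRUE)
  if (length(cc) < 2L) stop_domain("centile table needs at least two centile columns")
  pct <- as.numeric(sub("^c", "", cc))
  cc <- cc[order(pct)]; pct <- sort(pct)
  rows <- rows[order(rows$cov_value), , drop = FALSE]
  vals <- as.matrix(rows[, cc])
  if (any(apply(vals, 1L, function(v) any(diff(v) < 0))))
    stop_domain("centile values must be non-decreasing across centiles")
  structure(list(rows = rows, centile_cols = cc, centile_pct = pct,
                 covariate = covariate, sex = sex, parameter_id = parameter_id,
                 units = units, citation = citation),
            class = "centile_table")
}

#' @export
print.centile_table <- function(x, ...) {
  cat(sprintf("Centile table: %s (%s), %s, centiles %s by %s [%g, %g]\n",
              x$parameter_id, x$units, x$sex,
              paste(x$centile_pct, collapse = "/"), x$covariate,
              min(x$rows$cov_value), max(x$rows$cov_value)))
  invisible(x)
}

#' Centile band of a measurement in a printed centile table
#'
#' The row at the requested covariate value is obtained by linear
#' interpolation across the covariate, and the measurement is bracketed
#' between adjacent centile columns. An approximate continuous centile is
#' also returned (linear interpolation on the centile scale within the
#' bracketing pair; clamped at the outer columns).
#'
#' @param table a [centile_table].
#' @param value covariate value (within the table's range).
#' @param x measured value in table units.
#' @return list with `band` (e.g. `"25th-50th"`, `"<5th"`), `centile`
#'   (approximate, `NA` outside the outer columns) and `row` (the
#'   interpolated centile values).
#' @export
centile_band <- function(table, value, x) {
  stopifnot(inherits(table, "centile_table"), is_num1(value), is_num1(x))
  r <- table$rows
  if (value < min(r$cov_value) || value > max(r$cov_value))
    stop_domain(sprintf("covariate %g outside the table range [%g, %g]",
                        value, min(r$cov_value), max(r$cov_value)))
  row <- vapply(table$centile_cols,
                function(cl) stats::approx(r$cov_value, r[[cl]], value)$y,
                numeric(1))
  pct <- table$centile_pct
  lab <- function(p) paste0(p, switch(as.character(p %% 10),
                                      "1" = "st", "2" = "nd", "3" = "rd", "th"))
  if (x < row[1]) {
    return(list(band = paste0("<", lab(pct[1])), centile = NA_real_, row = row))
  }
  if (x > row[length(row)]) {
    return(list(band = paste0(">", lab(pct[length(pct)])),
                centile = NA_real_, row = row))
  }
  # x sits in [row[i], row[i+1]] for some i (row is non-decreasing)
  i <- max(which(row <= x))
  if (row[i] == x && i <= length(row)) {
    # exactly on a printed centile (take the largest matching column)
    cent <- pct[i]
    band <- lab(pct[i])
  } else {
    frac <- (x - row[i]) / (row[i + 1] - row[i])
    cent <- pct[i] + frac * (pct[i + 1] - pct[i])
    band <- paste0(lab(pct[i]), "-", lab(pct[i + 1]))
  }
  list(band = band, centile = cent, row = row)
}
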