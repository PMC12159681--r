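#' Reference range from a single study's mean and SD
#'
#' The single-study rule used throughout normative CMR compilations: the
#' central 95% of a Gaussian population is approximated by the mean plus or
#' minus twice the standard deviation, with limits rounded half away from
#' zero at the printed precision.
#'
#' @param mean study mean, in parameter units.
#' @param sd study standard deviation (non-negative).
#' @param k_sd multiple of the SD defining the limits (default 2).
#' @param decimals rounding precision for the limits; `NA` leaves the limits
#'   unrounded.
#' @return a `cmr_range` object with fields `lower`, `upper`, `mean`, `sd`,
#'   `n_total`, `method` and `precision`.
#' @export
#' @examples
#' mean_sd_range(250, 32)      # 186 - 314
#' mean_sd_range(43, 4.5)      # 34 - 52
mean_sd_range <- function(mean, sd, k_sd = 2, decimals = 0) {
  stopifnot(is_num1(mean), is.numeric(sd), length(sd) == 1L)
  if (!is.finite(sd) || sd < 0) stop_domain("`sd` must be a non-negative number")
  r <- new_range(mean - k_sd * sd, mean + k_sd * sd,
                 mean = mean, sd = sd, n_total = NA_integer_,
                 method = "single_study_mean_2sd", precision = decimals)
  if (!is.na(decimals)) r <- round_limits(r, decimals) else r
}

new_range <- function(lower, upper, mean = NA_real_, sd = NA_real_,
                      n_total = NA_integer_, method = NA_character_,
                      precision = NA_integer_) {
  stopifnot(lower <= upper)
  structure(list(lower = lower, upper = upper, mean = mean, sd = sd,
                 n_total = n_total, method = method, precision = precision),
            class = "cmr_range")
}

#' @export
print.cmr_range <- function(x, ...) {
  cat(sprintf("Reference range [%s]: %g - %g", x$method, x$lower, x$upper))
  if (!is.na(x$mean)) cat(sprintf("  (mean %g, sd %g)", x$mean, x$sd))
  cat("\n")
  invisible(x)
}

#' Round reference limits to the printed precision
#'
#' Both limits are rounded half away from zero; the operation is idempotent.
#'
#' @param range a `cmr_range`.
#' @param decimals number of decimal places.
#' @return the range with rounded limits and updated `precision`.
#' @export
round_limits <- function(range, decimals = 0) {
  stopifnot(inherits(range, "cmr_range"))
  range$lower <- round_half_away(range$lower, decimals)
  range$upper <- round_half_away(range$upper, decimals)
  range$precision <- decimals
  range
}

#' Random-effects pooling of study-level aggregates
#'
#' Combines per-study (n, mean, SD) triples for one parameter under the
#' standard random-effects model: true study means vary around a population
#' mean with between-study variance tau^2, and each observed study mean has
#' within-study variance sd^2/n. tau^2 is estimated by the DerSimonian-Laird
#' moment estimator, truncated at zero.
#'
#' @param studies data frame with numeric columns `n`, `mean`, `sd` (one row
#'   per study); a `parameter_id` column, when present, must be constant.
#' @return a `cmr_pooled` object with fields `mu_hat`, `se_mu`, `tau2`,
#'   `sigma2_within` (the sample-size-weighted pooled within-study variance),
#'   `k` and `n_total`.
#' @export
#' @examples
#' s <- data.frame(n = c(120, 85, 240), mean = c(146, 150, 148), sd = c(30, 35, 32))
#' pool_random_effects(s)
pool_random_effects <- function(studies) {
  stopifnot(is.data.frame(studies), all(c("n", "mean", "sd") %in% names(studies)))
  if (nrow(studies) == 0L) stop_domain("empty input: at least one study is required")
  if ("parameter_id" %in% names(studies) &&
      length(unique(studies$parameter_id)) > 1L)
    stop_domain("studies mix parameters: ",
                paste(unique(studies$parameter_id), collapse = ", "))
  n <- as.numeric(studies$n); y <- as.numeric(studies$mean)
  s <- as.numeric(studies$sd)
  if (any(!is.finite(n) | n < 2)) stop_domain("every study needs n >= 2")
  if (any(!is.finite(s) | s < 0)) stop_domain("negative or missing study sd")
  k <- length(y)
  vi <- s^2 / n
  w <- 1 / vi
  tau2 <- 0
  if (k > 1L) {
    yw <- sum(w * y) / sum(w)
    q <- sum(w * (y - yw)^2)
    cc <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / cc)
  }
  ws <- 1 / (vi + tau2)
  mu <- sum(ws * y) / sum(ws)
  structure(list(mu_hat = mu,
                 se_mu = sqrt(1 / sum(ws)),
                 tau2 = tau2,
                 sigma2_within = sum((n - 1) * s^2) / sum(n - 1),
                 k = k,
                 n_total = sum(n)),
            class = "cmr_pooled")
}

#' @export
print.cmr_pooled <- function(x, ...) {
  cat(sprintf("Pooled estimate over %d studies (n = %d):\n", x$k, x$n_total))
  cat(sprintf("  mu = %.4g (se %.3g), tau2 = %.4g, within-study sd = %.4g\n",
              x$mu_hat, x$se_mu, x$tau2, sqrt(x$sigma2_within)))
  invisible(x)
}

#' Frequentist 95% reference range around a pooled estimate
#'
#' Estimates the 0.025 and 0.975 population quantiles from aggregated data:
#' the pooled mean plus or minus the normal quantile times the estimated total
#' population SD, `sqrt(sigma2_within + tau2)`. The `"t"` variant additionally
#' propagates the uncertainty of the pooled mean, using a t quantile with
#' k - 1 degrees of freedom and half-width
#' `t * sqrt(sigma2_within + tau2 + se_mu^2)`.
#'
#' @param est a `cmr_pooled` object.
#' @param level coverage level in (0, 1); default 0.95.
#' @param decimals rounding precision; `NA` leaves limits unrounded.
#' @param variant `"normal"` (default) or `"t"`.
#' @return a `cmr_range` with method `"pooled_frequentist"`; its `sd` field is
#'   `sqrt(sigma2_within + tau2)`.
#' @export
frequentist_reference_range <- function(est, level = 0.95, decimals = NA,
                                        variant = c("normal", "t")) {
  stopifnot(inherits(est, "cmr_pooled"))
  variant <- match.arg(variant)
  if (!is_num1(level) || level <= 0 || level >= 1)
    stop_domain("`level` must be in (0, 1)")
  sd_pop <- sqrt(est$sigma2_within + est$tau2)
  half <- if (variant == "normal") {
    stats::qnorm((1 + level) / 2) * sd_pop
  } else {
    if (est$k < 2L) stop_domain("t variant needs at least 2 studies")
    stats::qt((1 + level) / 2, df = est$k - 1) *
      sqrt(est$sigma2_within + est$tau2 + est$se_mu^2)
  }
  r <- new_range(est$mu_hat - half, est$mu_hat + half,
                 mean = est$mu_hat, sd = sd_pop, n_total = est$n_total,
                 method = "pooled_frequentist", precision = decimals)
  if (!is.na(decimals)) round_limits(r, decimals) else r
}

#' Study inclusion rule for reference-range calculation
#'
#' A study contributes to reference ranges only with at least 40 subjects
#' (per sex stratum when sex-specific ranges are required).
#'
#' @param n number of subjects in the study (or in the sex stratum when
#'   `per_sex` is `TRUE`); vectorized.
#' @param per_sex whether the count refers to a single sex stratum.
#' @return data frame with logical `accepted` and a `reason` string.
#' @export
#' @examples
#' eligibility_filter(c(39, 40, 1000))
eligibility_filter <- function(n, per_sex = FALSE) {
  stopifnot(is.numeric(n))
  ok <- n >= 40
  what <- if (per_sex) "subjects per sex" else "subjects"
  data.frame(
    n = n,
    accepted = ok,
    reason = ifelse(ok,
                    sprintf("n = %d meets the minimum of 40 %s", n, what),
                    sprintf("n = %d is below the minimum of 40 %s", n, what)),
    stringsAsFactors = FALSE
  )
}
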