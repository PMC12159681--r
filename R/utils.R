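#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with ties going away from zero,
#' the convention used when reference limits are reported at the printed
#' precision of the measurement (e.g. 22.2 -> 22 and 32.6 -> 33 at 0 dp, but
#' also 22.5 -> 23 and -22.5 -> -23). This differs from [base::round()], which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits non-negative integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_away(c(22.2, 32.6, 2.5, -2.5), 0)
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# scalar finite-number check used by the formula toolkit
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_domain <- function(...) stop(..., call. = FALSE)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators behave as pure functions of (params, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
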