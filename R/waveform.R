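#' Construct a velocity-time flow curve
#'
#' @param times sample times in ms; at least 10 samples, strictly increasing,
#'   uniformly spaced (relative tolerance 1e-6).
#' @param velocities velocities in cm/s, same length.
#' @param site free-text site label.
#' @return a `flow_curve` object.
#' @export
flow_curve <- function(times, velocities, site = "") {
  stopifnot(is.numeric(times), is.numeric(velocities),
            length(times) == length(velocities))
  if (length(times) < 10L) stop_domain("a flow curve needs at least 10 samples")
  dt <- diff(times)
  if (any(dt <= 0)) stop_domain("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop_domain("times must be uniformly spaced")
  structure(list(times = times, velocities = velocities,
                 dt = mean(dt), site = site),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("Flow curve '%s': %d samples at %.3g ms, velocity %.3g to %.3g cm/s\n",
              x$site, length(x$times), x$dt,
              min(x$velocities), max(x$velocities)))
  invisible(x)
}

#' Construct a proximal/distal aortic waveform pair
#'
#' @param proximal,distal [flow_curve]s with matching sampling rates.
#' @param delta_x centerline path length between the two sites, m (> 0).
#' @return an `aorta_path_pair` object.
#' @export
aorta_path_pair <- function(proximal, distal, delta_x) {
  stopifnot(inherits(proximal, "flow_curve"), inherits(distal, "flow_curve"))
  if (!is_num1(delta_x) || delta_x <= 0) stop_domain("`delta_x` must be positive")
  if (abs(proximal$dt - distal$dt) > 1e-6 * proximal$dt)
    stop_domain("proximal and distal curves must share the sampling rate")
  structure(list(proximal = proximal, distal = distal, delta_x = delta_x),
            class = "aorta_path_pair")
}

# Foot (wave arrival time) of a single systolic waveform.
#
# upslope_intersect: the pre-systolic baseline is the median of samples below
# 10% normalized amplitude preceding the peak; a least-squares line through
# the samples with normalized amplitude in [0.20, 0.80] on the rising limb
# (earliest contiguous run) is intersected with that baseline.
# upslope_midpoint: the time at 50% amplitude on the rising limb, linearly
# interpolated.
wave_foot <- function(curve, method = c("upslope_intersect", "upslope_midpoint"),
                      min_amplitude = 1e-6) {
  method <- match.arg(method)
  t <- curve$times; v <- curve$velocities
  ipk <- which.max(v)
  base0 <- min(v[seq_len(ipk)])
  amp0 <- v[ipk] - base0
  if (!(amp0 > min_amplitude))
    stop_domain("no detectable systolic upstroke (flat curve)")
  a <- (v - base0) / amp0
  pre <- which(a[seq_len(ipk)] < 0.10)
  baseline <- if (length(pre)) stats::median(v[pre]) else base0
  amp <- v[ipk] - baseline
  if (!(amp > min_amplitude))
    stop_domain("no detectable systolic upstroke above the baseline")
  a <- (v - baseline) / amp
  if (method == "upslope_midpoint") {
    # first crossing of 0.5 before the peak
    below <- which(a[seq_len(ipk)] < 0.5)
    if (!length(below)) stop_domain("no 50%-amplitude crossing before the peak")
    i <- max(below)
    if (i == ipk) stop_domain("no 50%-amplitude crossing before the peak")
    frac <- (0.5 - a[i]) / (a[i + 1] - a[i])
    return(t[i] + frac * (t[i + 1] - t[i]))
  }
  in_band <- which(a >= 0.20 & a <= 0.80)
  in_band <- in_band[in_band <= ipk]
  if (length(in_band) < 2L)
    stop_domain("fewer than two samples in the 20-80% upslope band")
  # earliest contiguous run
  runs <- split(in_band, cumsum(c(1, diff(in_band) != 1)))
  run <- runs[[1]]
  if (length(run) < 2L) run <- in_band  # degenerate: pool all band samples
  fit <- stats::lm.fit(cbind(1, t[run]), v[run])
  slope <- fit$coefficients[2]; icpt <- fit$coefficients[1]
  if (!is.finite(slope) || slope <= 0)
    stop_domain("upslope regression failed (non-positive slope)")
  as.numeric((baseline - icpt) / slope)
}

#' Foot-to-foot transit time between two flow curves
#'
#' Estimates the arrival-time difference of the systolic wave front between
#' the proximal and the distal site. The default method intersects a linear
#' regression through the 20-80%-amplitude rising limb with the constant
#' pre-systolic baseline (median of pre-upstroke samples below 10%
#' amplitude); the alternative takes the time at 50% amplitude on the
#' upstroke.
#'
#' @param pair an [aorta_path_pair].
#' @param method `"upslope_intersect"` (default) or `"upslope_midpoint"`.
#' @param min_amplitude detection threshold on the peak-to-baseline
#'   amplitude, in velocity units.
#' @return list with `dt_ms`, `foot_proximal`, `foot_distal` and a `flagged`
#'   logical set when the transit time is non-positive.
#' @export
transit_time <- function(pair, method = c("upslope_intersect", "upslope_midpoint"),
                         min_amplitude = 1e-6) {
  stopifnot(inherits(pair, "aorta_path_pair"))
  method <- match.arg(method)
  fp <- wave_foot(pair$proximal, method, min_amplitude)
  fd <- wave_foot(pair$distal, method, min_amplitude)
  dt <- fd - fp
  list(dt_ms = dt, foot_proximal = fp, foot_distal = fd, flagged = dt <= 0)
}

#' Pulse wave velocity from a waveform pair
#'
#' `PWV = delta_x / delta_t`, with the transit time from [transit_time()].
#'
#' @inheritParams transit_time
#' @return list with `pwv_ms` (m/s), `dt_ms` and the per-curve feet.
#' @export
#' @examples
#' pair <- gen_flow_pair(true_pwv = 8, delta_x = 0.4, dt = 4, seed = 1)
#' pwv(pair)$pwv_ms
pwv <- function(pair, method = c("upslope_intersect", "upslope_midpoint"),
                min_amplitude = 1e-6) {
  tt <- transit_time(pair, method, min_amplitude)
  if (tt$dt_ms <= 0)
    stop_domain(sprintf(
      "non-positive transit time (feet: proximal %.2f ms, distal %.2f ms)",
      tt$foot_proximal, tt$foot_distal))
  c(list(pwv_ms = pair$delta_x / (tt$dt_ms / 1000)), tt)
}
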