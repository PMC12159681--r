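#' Simulate study-level aggregates under the random-effects model
#'
#' Draws true study means from Normal(mu, tau^2), individual measurements
#' from Normal(study mean, sigma_within^2), and reports each study's sample
#' size, sample mean and sample SD — the aggregate triples a reference-value
#' meta-analysis consumes. Generators are pure functions of their parameters
#' and seed; the caller's RNG state is left untouched.
#'
#' @param mu true population mean.
#' @param sigma_within within-study SD (> 0).
#' @param tau between-study SD (>= 0).
#' @param k_studies number of studies (>= 1).
#' @param n_range subjects per study: a single count or a `c(min, max)` range
#'   sampled uniformly.
#' @param seed integer seed.
#' @param parameter_id label written into the output.
#' @return data frame of study summaries (`study_id`, `parameter_id`, `sex`,
#'   `n`, `mean`, `sd`) with the true study means in
#'   `attr(, "theta")`.
#' @export
gen_study_aggregates <- function(mu, sigma_within, tau = 0, k_studies = 10,
                                 n_range = 200, seed = NULL,
                                 parameter_id = "synthetic") {
  stopifnot(is_num1(mu), is_num1(sigma_within), sigma_within > 0,
            is_num1(tau), tau >= 0, k_studies >= 1)
  if (length(n_range) == 1L) n_range <- c(n_range, n_range)
  stopifnot(n_range[1] >= 2)
  with_seed(seed, {
    n <- if (n_range[1] == n_range[2]) rep(n_range[1], k_studies)
         else sample(seq(n_range[1], n_range[2]), k_studies, replace = TRUE)
    theta <- stats::rnorm(k_studies, mu, tau)
    m <- s <- numeric(k_studies)
    for (i in seq_len(k_studies)) {
      x <- stats::rnorm(n[i], theta[i], sigma_within)
      m[i] <- mean(x); s[i] <- stats::sd(x)
    }
    out <- data.frame(study_id = sprintf("sim%02d", seq_len(k_studies)),
                      parameter_id = parameter_id, sex = "all",
                      n = n, mean = m, sd = s, stringsAsFactors = FALSE)
    attr(out, "theta") <- theta
    out
  })
}

#' Sample a population from an LMS growth model
#'
#' Inverse sampling: draws z ~ N(0, 1) and maps through
#' `x = M * (1 + L*S*z)^(1/L)`. Draws violating the feasibility constraint
#' `1 + L*S*z > 0` are rejected and redrawn (none occur for the parameter
#' ranges of the packaged pediatric tables).
#'
#' @param L,M,S LMS parameters.
#' @param n sample size.
#' @param seed integer seed.
#' @return list with `values`, the generating `z` scores and `n_rejected`.
#' @export
gen_lms_population <- function(L, M, S, n, seed = NULL) {
  stopifnot(is_num1(L), is_num1(M), M > 0, is_num1(S), S > 0, n >= 1)
  with_seed(seed, {
    z <- stats::rnorm(n)
    rejected <- 0L
    if (abs(L) >= 1e-7) {
      repeat {
        bad <- which(1 + L * S * z <= 0)
        if (!length(bad)) break
        rejected <- rejected + length(bad)
        z[bad] <- stats::rnorm(length(bad))
      }
    }
    list(values = lms_centile(z = z, L = L, M = M, S = S),
         z = z, n_rejected = rejected)
  })
}

# smooth systolic waveform template (velocity in cm/s as a function of ms):
# flat diastolic baseline, half-sine upstroke, half-cosine decay back to
# baseline, then flat until the end of the cycle.
flow_template <- function(t, t_foot = 200, upstroke_ms = 80, decay_ms = 300,
                          peak = 100, baseline = 5) {
  tt <- t %% 1000
  v <- rep(baseline, length(tt))
  up <- tt >= t_foot & tt < t_foot + upstroke_ms
  v[up] <- baseline + (peak - baseline) *
    sin(pi / 2 * (tt[up] - t_foot) / upstroke_ms)
  dn <- tt >= t_foot + upstroke_ms & tt < t_foot + upstroke_ms + decay_ms
  v[dn] <- baseline + (peak - baseline) *
    cos(pi / 2 * (tt[dn] - t_foot - upstroke_ms) / decay_ms)
  v
}

#' Simulate a proximal/distal aortic waveform pair
#'
#' Builds a smooth systolic template (80 ms half-sine upstroke, 300 ms decay,
#' 1000 ms cycle) and a copy delayed by `delta_x / true_pwv`, sampled every
#' `dt` ms, with optional multiplicative Gaussian noise.
#'
#' @param true_pwv ground-truth pulse wave velocity, m/s (> 0).
#' @param delta_x centerline distance between sites, m (> 0).
#' @param dt sampling interval, ms (> 0).
#' @param noise_sd multiplicative noise SD as a fraction of the local value.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param peak systolic peak velocity, cm/s.
#' @return an [aorta_path_pair] with the ground truth in
#'   `attr(, "truth")` (`true_pwv`, `delay_ms`).
#' @export
gen_flow_pair <- function(true_pwv, delta_x = 0.3, dt = 5, noise_sd = 0,
                          seed = NULL, peak = 100) {
  stopifnot(is_num1(true_pwv), true_pwv > 0, is_num1(delta_x), delta_x > 0,
            is_num1(dt), dt > 0, noise_sd >= 0)
  delay <- delta_x / true_pwv * 1000  # ms
  if (delay < dt)
    warning(sprintf("delay (%.2f ms) below the sampling interval (%g ms)",
                    delay, dt))
  t <- seq(0, 1000 - dt, by = dt)
  vp <- flow_template(t, peak = peak)
  vd <- flow_template(t - delay, peak = peak)
  if (noise_sd > 0) {
    with_seed(seed, {
      vp <- vp * (1 + stats::rnorm(length(vp), 0, noise_sd))
      vd <- vd * (1 + stats::rnorm(length(vd), 0, noise_sd))
    })
  }
  pair <- aorta_path_pair(flow_curve(t, vp, "proximal"),
                          flow_curve(t, vd, "distal"), delta_x)
  attr(pair, "truth") <- list(true_pwv = true_pwv, delay_ms = delay)
  pair
}

#' Rasterize reference shapes for box-counting tests
#'
#' Produces binary images of known fractal dimension: a straight 1-px line
#' (FD 1), the Koch curve (FD log4/log3), the boundary of a square (FD 1)
#' and a filled square (FD 2). The Koch curve is built by iterated segment
#' replacement and rasterized by dense sampling along each segment.
#'
#' @param kind `"line"`, `"koch"`, `"square_boundary"` or `"filled_square"`.
#' @param iterations Koch iteration depth.
#' @param size_px image width in px (>= 64).
#' @param seed accepted for generator-interface uniformity; the shapes are
#'   deterministic and the seed is unused.
#' @return logical matrix.
#' @export
gen_fractal_image <- function(kind = c("line", "koch", "square_boundary",
                                       "filled_square"),
                              iterations = 5, size_px = 512, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(size_px >= 64)
  if (kind == "line") {
    img <- matrix(FALSE, size_px, size_px)
    img[floor(size_px / 2), ] <- TRUE
    return(img)
  }
  if (kind == "square_boundary" || kind == "filled_square") {
    img <- matrix(FALSE, size_px, size_px)
    lo <- floor(size_px / 4); hi <- lo + floor(size_px / 2)
    if (kind == "filled_square") {
      img[lo:hi, lo:hi] <- TRUE
    } else {
      img[lo:hi, c(lo, hi)] <- TRUE
      img[c(lo, hi), lo:hi] <- TRUE
    }
    return(img)
  }
  # Koch curve on [0, 1]
  pts <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  for (it in seq_len(iterations)) {
    new <- matrix(0, nrow = (nrow(pts) - 1) * 4 + 1, ncol = 2)
    k <- 1L
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      d <- (b - a) / 3
      p1 <- a + d; p3 <- a + 2 * d
      # apex of the equilateral bump (rotate d by +60 degrees)
      p2 <- p1 + c(d[1] * 0.5 - d[2] * sqrt(3) / 2,
                   d[1] * sqrt(3) / 2 + d[2] * 0.5)
      new[k, ] <- a; new[k + 1, ] <- p1; new[k + 2, ] <- p2; new[k + 3, ] <- p3
      k <- k + 4L
    }
    new[k, ] <- pts[nrow(pts), ]
    pts <- new
  }
  w <- size_px
  h <- ceiling(size_px * 0.45)
  img <- matrix(FALSE, h, w)
  scale <- (w - 2)
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len_px <- max(1, ceiling(sqrt(sum((b - a)^2)) * scale))
    s <- seq(0, 1, length.out = 2 * len_px + 1)
    xs <- round(1 + (a[1] + s * (b[1] - a[1])) * scale) + 1
    ys <- round(1 + (a[2] + s * (b[2] - a[2])) * scale) + 1
    keep <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
    img[cbind(ys[keep], xs[keep])] <- TRUE
  }
  img
}
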