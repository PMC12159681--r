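test_that("mean +/- 2 SD ranges reproduce printed single-study limits", {
  cases <- list(
    # mean, sd, decimals, lower, upper
    list(250, 32, 0, 186, 314),    # athlete LVEDV, men
    list(113, 17, 0, 79, 147),     # elite athlete LVM/BSA, men
    list(219, 35, 0, 149, 289),    # elite athlete RVEDV, women
    list(1017, 48, 0, 921, 1113),  # pediatric native T1, 1.5T
    list(43, 4.5, 0, 34, 52)       # pediatric T2
  )
  for (cs in cases) {
    r <- mean_sd_range(cs[[1]], cs[[2]], decimals = cs[[3]])
    expect_equal(r$lower, cs[[4]])
    expect_equal(r$upper, cs[[5]])
    expect_identical(r$method, "single_study_mean_2sd")
  }
})

test_that("mean_sd_range is symmetric before rounding and handles sd = 0", {
  r <- mean_sd_range(73.2, 5.17, decimals = NA)
  expect_equal(r$mean - r$lower, r$upper - r$mean)
  r0 <- mean_sd_range(42, 0)
  expect_equal(r0$lower, 42)
  expect_equal(r0$upper, 42)
  expect_error(mean_sd_range(10, -1), "non-negative")
})

test_that("limits are rounded half away from zero, idempotently", {
  # 27.4 +/- 2*2.6 = (22.2, 32.6) -> printed 22-33
  r <- round_limits(new_range <- mean_sd_range(27.4, 2.6, decimals = NA), 0)
  expect_equal(c(r$lower, r$upper), c(22, 33))
  r2 <- round_limits(mean_sd_range(9, 1.6, decimals = NA), 0)  # (5.8, 12.2)
  expect_equal(c(r2$lower, r2$upper), c(6, 12))
  expect_equal(round_half_away(c(2.5, -2.5, 0.345), c(0, 0, 2)[1]),
               c(3, -3, 0))
  # idempotence
  expect_identical(round_limits(r, 0)[c("lower", "upper")],
                   r[c("lower", "upper")])
})

test_that("DL pooling matches the brute-force oracle and metafor", {
  s <- five_studies()
  est <- pool_random_effects(s)
  o <- dl_oracle(s$n, s$mean, s$sd)
  expect_equal(est$mu_hat, o$mu, tolerance = 1e-10)
  expect_equal(est$tau2, o$tau2, tolerance = 1e-10)
  expect_equal(est$se_mu, o$se, tolerance = 1e-10)
  expect_equal(est$sigma2_within, o$sigma2_within, tolerance = 1e-10)
  skip_if_not_installed("metafor")
  m <- metafor::rma(yi = s$mean, vi = s$sd^2 / s$n, method = "DL")
  expect_equal(est$mu_hat, as.numeric(m$b), tolerance = 1e-8)
  expect_equal(est$tau2, m$tau2, tolerance = 1e-8)
  expect_equal(est$se_mu, m$se, tolerance = 1e-8)
})

test_that("pooling degenerate cases behave as the model demands", {
  # two identical studies: homogeneity
  s <- data.frame(n = c(100, 100), mean = c(50, 50), sd = c(8, 8))
  est <- pool_random_effects(s)
  expect_equal(est$mu_hat, 50)
  expect_equal(est$tau2, 0)
  expect_equal(est$sigma2_within, 64)
  # single study
  e1 <- pool_random_effects(data.frame(n = 80, mean = 42, sd = 5))
  expect_equal(e1$mu_hat, 42)
  expect_equal(e1$tau2, 0)
  # input validation
  expect_error(pool_random_effects(data.frame(n = 1, mean = 1, sd = 1)),
               "n >= 2")
  expect_error(pool_random_effects(five_studies()[0, ]), "empty")
  mixed <- five_studies(); mixed$parameter_id[2] <- "lvef"
  expect_error(pool_random_effects(mixed), "mix")
})

test_that("pooled mean lies within the study means and ignores study order", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    s <- data.frame(n = sample(40:400, k, TRUE),
                    mean = rnorm(k, 100, 12), sd = runif(k, 5, 30))
    est <- pool_random_effects(s)
    expect_gte(est$mu_hat, min(s$mean))
    expect_lte(est$mu_hat, max(s$mean))
    perm <- pool_random_effects(s[sample(k), ])
    expect_equal(est$mu_hat, perm$mu_hat, tolerance = 1e-12)
    expect_equal(est$tau2, perm$tau2, tolerance = 1e-12)
  }
})

test_that("frequentist range collapses to normal quantiles when tau2 = 0", {
  s <- data.frame(n = c(200, 200), mean = c(100, 100), sd = c(15, 15))
  est <- pool_random_effects(s)
  r <- frequentist_reference_range(est, decimals = NA)
  expect_equal(est$tau2, 0)
  expect_equal(r$lower, 100 - qnorm(0.975) * 15, tolerance = 1e-9)
  expect_equal(r$upper, 100 + qnorm(0.975) * 15, tolerance = 1e-9)
  # equals mean_sd_range with k_sd = z_0.975 under homogeneity
  m <- mean_sd_range(100, 15, k_sd = qnorm(0.975), decimals = NA)
  expect_equal(c(r$lower, r$upper), c(m$lower, m$upper), tolerance = 1e-9)
})

test_that("frequentist range matches hand computation on the 5-study fixture", {
  est <- pool_random_effects(five_studies())
  r <- frequentist_reference_range(est, decimals = NA)
  o <- dl_oracle(five_studies()$n, five_studies()$mean, five_studies()$sd)
  half <- qnorm(0.975) * sqrt(o$sigma2_within + o$tau2)
  expect_equal(r$lower, o$mu - half, tolerance = 1e-9)
  expect_equal(r$upper, o$mu + half, tolerance = 1e-9)
  expect_equal(r$sd, sqrt(o$sigma2_within + o$tau2), tolerance = 1e-9)
  expect_identical(r$method, "pooled_frequentist")
})

test_that("range width is non-decreasing in tau2, all else fixed", {
  est <- pool_random_effects(five_studies())
  widths <- vapply(c(0, 1, 10, 100), function(t2) {
    e <- est; e$tau2 <- t2
    r <- frequentist_reference_range(e, decimals = NA)
    r$upper - r$lower
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("the t-quantile variant widens the range and validates its inputs", {
  est <- pool_random_effects(five_studies())
  rn <- frequentist_reference_range(est, decimals = NA)
  rt <- frequentist_reference_range(est, decimals = NA, variant = "t")
  expect_gt(rt$upper - rt$lower, rn$upper - rn$lower)
  expect_error(frequentist_reference_range(est, level = 1), "level")
  expect_error(frequentist_reference_range(est, level = 0), "level")
})

test_that("the 40-subject inclusion rule is applied at the boundary", {
  f <- eligibility_filter(c(39, 40, 1000))
  expect_identical(f$accepted, c(FALSE, TRUE, TRUE))
  expect_match(f$reason[1], "below the minimum")
  expect_match(eligibility_filter(39, per_sex = TRUE)$reason, "per sex")
})
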