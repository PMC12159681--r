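# Independent textbook implementation of DerSimonian-Laird pooling, written
# step by step with explicit loops so it shares no code path with the
# package. Used as the oracle for pool_random_effects().
dl_oracle <- function(n, m, s) {
  k <- length(m)
  vi <- numeric(k)
  for (i in seq_len(k)) vi[i] <- s[i]^2 / n[i]
  w <- 1 / vi
  ybar <- 0
  for (i in seq_len(k)) ybar <- ybar + w[i] * m[i]
  ybar <- ybar / sum(w)
  q <- 0
  for (i in seq_len(k)) q <- q + w[i] * (m[i] - ybar)^2
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- (q - (k - 1)) / cc
  if (tau2 < 0) tau2 <- 0
  ws <- 1 / (vi + tau2)
  mu <- 0
  for (i in seq_len(k)) mu <- mu + ws[i] * m[i]
  mu <- mu / sum(ws)
  num <- den <- 0
  for (i in seq_len(k)) {
    num <- num + (n[i] - 1) * s[i]^2
    den <- den + (n[i] - 1)
  }
  list(mu = mu, tau2 = tau2, se = 1 / sqrt(sum(ws)),
       sigma2_within = num / den)
}

# heterogeneous 5-study fixture shared across pooling tests
five_studies <- function() {
  data.frame(study_id = paste0("s", 1:5),
             parameter_id = "lvedv",
             n = c(120, 85, 240, 60, 400),
             mean = c(146, 152, 148, 139, 150),
             sd = c(30, 35, 32, 28, 31),
             stringsAsFactors = FALSE)
}

# packaged registry, loaded once per test session
pkg_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- load_registry()
    reg
  }
})

# boys age-6 LMS row of the packaged maximal-LA-volume table
LMS_BOY6 <- list(L = 1.378, M = 36.715, S = 0.263)
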