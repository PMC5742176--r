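test_that("profile is the cumulative sum of the centered series", {
  expect_equal(dfa_profile(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(dfa_profile(c(1, -1, 1, -1)), c(1, 0, 1, 0))
})

test_that("profiling twice adds -4 to the periodogram slope of white noise", {
  slopes <- vapply(1:10, function(s) {
    w <- colored_noise(8192, 0, seed = 400 + s)
    periodogram_slope(dfa_profile(dfa_profile(w)))
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-4)), 0.3)
})

test_that("sub-band detrending is a linear DC-killing operator", {
  expect_equal(subband_detrend(rep(3.7, 256), l = 8), rep(0, 256),
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(512); y <- rnorm(512); a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(subband_detrend(a * x + b * y, 16),
                 a * subband_detrend(x, 16) + b * subband_detrend(y, 16),
                 tolerance = 1e-10)
  }
  # a slow sinusoid (period >> l) is almost fully removed
  t <- 1:4096
  s <- sin(2 * pi * t / 1024)
  out <- subband_detrend(s, l = 8)
  expect_lt(stats::sd(out) / stats::sd(s), 0.10)
})

test_that("window counts and variances follow the 50%-overlap rule", {
  v <- window_variances(rnorm(32), l = 8)
  expect_length(v, 3)           # floor(32/8) - 1
  expect_equal(window_variances(rep(2, 64), 8), rep(0, 7))
  # variance is shift-invariant
  x <- rnorm(128)
  expect_equal(window_variances(x, 8), window_variances(x + 5, 8),
               tolerance = 1e-10)
  expect_error(window_variances(rnorm(10), 8), "scale too large")
})

test_that("partition function and weights match hand arithmetic", {
  expect_identical(partition_function(rep(0.3, 7), 0), 7)
  expect_identical(partition_function(c(1, 4, 9), 2), 14)
  expect_identical(partition_function(c(4, 9), 1), 5)
  expect_error(partition_function(c(0, 1), -2), "degenerate")

  expect_equal(mu_weights(c(2, 5, 9, 0.1), 0), rep(0.25, 4))
  expect_equal(mu_weights(rep(1, 4), 1.7), rep(0.25, 4))
  expect_equal(mu_weights(c(1, 3), 2), c(0.25, 0.75))
})

test_that("weights normalize to one for any q", {
  set.seed(33)
  for (i in 1:20) {
    v <- rexp(sample(4:30, 1))
    q <- runif(1, -3, 3)
    expect_equal(sum(mu_weights(v, q)), 1, tolerance = 1e-12)
  }
})

test_that("chi(0, l) equals the window count exactly", {
  x <- colored_noise(1024, 1, seed = 2)
  y <- dfa_profile(x)
  for (l in c(8, 16, 32)) {
    v <- window_variances(subband_detrend(y, l), l)
    expect_identical(partition_function(v, 0), as.double(1024 %/% l - 1))
  }
})

test_that("colored-noise taxonomy: white/brown series give alpha 0.5/1.5", {
  white <- vapply(1:30, function(s)
    alpha0(colored_noise(4096, 0, seed = s))$alpha0, numeric(1))
  expect_lt(abs(mean(white) - 0.5), 0.05)

  brown <- vapply(1:30, function(s)
    alpha0(cumsum(colored_noise(4096, 0, seed = 500 + s)))$alpha0,
    numeric(1))
  expect_lt(abs(mean(brown) - 1.5), 0.07)
})

test_that("single long white-noise series: alpha(0) near 0.5, f(0) near 1", {
  fit <- mfdfa(colored_noise(8192, 0, seed = 77))
  expect_lt(abs(fit$alpha0 - 0.5), 0.1)
  expect_lt(abs(fit$f[fit$q == 0] - 1), 0.15)
  expect_gt(fit$alpha0_r2, 0.98)
})

test_that("monofractal input gives a flat alpha(q)", {
  fit <- mfdfa(colored_noise(8192, 1, seed = 13))
  expect_lt(max(fit$alpha) - min(fit$alpha), 0.2)
})

test_that("the estimator is affine-equivariant", {
  x <- colored_noise(2048, 1, seed = 6)
  f1 <- mfdfa(x)
  f2 <- mfdfa(3 * x + 7)
  expect_equal(f1$alpha0, f2$alpha0, tolerance = 1e-10)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)
  expect_equal(f1$f, f2$f, tolerance = 1e-10)
})

test_that("binomial cascade shows a wide, ordered, Legendre-consistent spectrum", {
  x <- binomial_cascade(12, p = 0.3, seed = 1)
  for (m in c("subband", "poly")) {
    fit <- mfdfa(x, method = m)
    expect_gt(fit$alpha[fit$q == -3] - fit$alpha[fit$q == 3], 0.3)
    expect_true(all(diff(fit$alpha) <= 0.05))   # non-increasing in q
    expect_lt(max(abs(fit$f - (fit$q * fit$alpha - fit$tau))), 0.1)
  }
})

test_that("sub-band and polynomial detrending agree on monofractal noise", {
  for (H in c(0.3, 0.5, 0.7)) {
    d <- vapply(1:20, function(s) {
      x <- colored_noise(2048, gamma_from_alpha(H), seed = 7000 * H + s)
      alpha0(x)$alpha0 - mfdfa(x, q = 0, method = "poly")$alpha0
    }, numeric(1))
    expect_lt(abs(mean(d)), 0.1)
  }
})

test_that("classical MFDFA reproduces the standard DFA benchmark", {
  fit <- mfdfa(colored_noise(8192, 0, seed = 55), method = "poly")
  expect_lt(abs(fit$h[fit$q == 2] - 0.5), 0.1)
})

test_that("scale bookkeeping: short series drop scales or error out", {
  # 90 intervals: only scales up to l = 18 keep >= 4 windows
  fit <- mfdfa(colored_noise(4096, 0, seed = 1)[1:90], q = 0)
  expect_identical(fit$scales, c(8L, 10L, 12L, 14L, 16L))
  expect_error(mfdfa(rnorm(40)), "insufficient scales|too short")
  expect_error(mfdfa(rnorm(2048), scales = c(8, 10, 12, 14)), "scales")
})

test_that("mfdfa methods expose the fit coherently", {
  fit <- mfdfa(colored_noise(2048, 1, seed = 9))
  expect_s3_class(fit, "mfdfa")
  expect_named(coef(fit), "alpha0")
  expect_length(coef(fit, "spectrum"), length(fit$q))
  s <- summary(fit)
  expect_s3_class(s, "summary.mfdfa")
  expect_equal(s$alpha0, fit$alpha0)
  expect_output(print(fit), "alpha\\(0\\)")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_length(sims[[1]], fit$n)
})
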