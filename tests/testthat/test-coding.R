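test_that("empirical correlation model matches closed-form toy cases", {
  # rank-1 two-channel toy
  m <- estimate_correlation(matrix(c(1, 1, -1, -1), 2, byrow = TRUE))
  expect_equal(m$R, matrix(1, 2, 2) * matrix(c(1, 1, 1, 1), 2),
               tolerance = 1e-12)
  expect_equal(m$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_error(estimate_correlation(matrix(1, 1, 3)), "2 samples")

  # iid unit-variance channels
  set.seed(9)
  m2 <- estimate_correlation(matrix(rnorm(1e5 * 6), ncol = 6))
  expect_lt(max(abs(m2$R - diag(6))), 0.02)
})

test_that("correlation model conventions hold: orthonormal, sorted, reconstructable", {
  ens <- make_spectral_ensemble(60, 200, seed = 21)
  m <- estimate_correlation(ens)
  U <- m$eigenvectors
  expect_lt(max(abs(U %*% t(U) - diag(60))), 1e-8)
  expect_false(is.unsorted(rev(m$eigenvalues)))
  expect_gte(min(m$eigenvalues), 0)
  recon <- t(U) %*% (m$eigenvalues * U)
  expect_lt(max(abs(recon - m$R)) / max(abs(m$R)), 1e-8)
  # sign convention: first non-negligible component positive
  for (k in c(1, 10, 40)) {
    v <- U[k, ]
    expect_gt(v[which(abs(v) > 1e-8 * max(abs(v)))[1]], 0)
  }
})

test_that("fourier decorrelation matches closed-form pairs and the eigen oracle", {
  # white (delta) correlation -> flat spectrum
  S <- fourier_decorrelate(c(2, rep(0, 15)))
  expect_equal(as.numeric(S), rep(2, 16), tolerance = 1e-12)

  # circular Gaussian lag correlation -> wrapped-Gaussian spectrum
  n <- 64
  lags <- pmin(0:(n - 1), n - (0:(n - 1)))
  r <- exp(-lags^2 / (2 * 4^2))
  S2 <- fourier_decorrelate(r)
  omega <- ecstrf:::dft_frequencies(n)
  # closed-form Fourier pair of the periodized Gaussian
  closed <- vapply(omega, function(w) {
    sum(exp(-(seq(-5 * n, 5 * n))^2 / (2 * 4^2)) *
          cos(2 * pi * w * seq(-5 * n, 5 * n)))
  }, numeric(1))
  expect_lt(max(abs(S2 - closed)), 1e-8 * max(closed))

  # spectrum equals sorted eigenvalues of the circulant correlation
  corr <- analytic_correlation(n_channels = n, intensity_scale = 2,
                               smoothing_length = 4, circular = TRUE)
  S3 <- fourier_decorrelate(corr$R[1, ])
  expect_equal(sort(as.numeric(S3), decreasing = TRUE), corr$eigenvalues,
               tolerance = 1e-8)

  expect_error(fourier_decorrelate(c(1, 0.5, 0.1, 0.2)), "symmetric")
})

test_that("channel information follows the Gaussian closed form", {
  ns <- default_noise()
  expect_equal(channel_information(0, 5, ns), 0)
  expect_equal(channel_information(1, 1, ns), 0.5 * log2(3 / 2),
               tolerance = 1e-12)
  # encoding-noise-free limit is independent of the gain
  ns0 <- noise_spec(1, 1e-12)
  expect_equal(channel_information(0.3, 4, ns0), 0.5 * log2(5),
               tolerance = 1e-6)
  expect_equal(channel_information(7, 4, ns0), 0.5 * log2(5),
               tolerance = 1e-6)
})

test_that("per-channel objective behaves at its boundaries", {
  ns <- default_noise()
  expect_equal(channel_objective(0, 3, ns, 5), ns$encoding_noise_var)
  expect_gt(channel_objective(100, 3, ns, 5), channel_objective(1, 3, ns, 5))
})

test_that("closed-form gain equals the numeric minimizer over random draws", {
  ns <- default_noise()
  # worked example: N = Ne = 1, lambda = 10, S = 10
  expect_equal(optimal_gain(10, ns, 10)^2, (sqrt(300) - 12) / 22,
               tolerance = 1e-10)
  # boundary example: S = 0.2 is below the activation threshold
  expect_identical(optimal_gain(0.2, ns, 10), 0)
  expect_identical(optimal_gain(0, ns, 10), 0)

  set.seed(31)
  for (i in 1:100) {
    S <- runif(1, 0, 20)
    N <- runif(1, 0.1, 3)
    Ne <- runif(1, 0.1, 3)
    lam <- runif(1, 0.5, 30)
    g_closed <- optimal_gain(S, noise_spec(N, Ne), lam)
    g_num <- numeric_optimal_gain(S, N, Ne, lam)
    if (g_num == 0) {
      expect_identical(g_closed, 0)
    } else {
      expect_lt(abs(g_closed - g_num) / g_num, 1e-6)
    }
    # soft threshold: g > 0 iff lambda > 2 Ne (1 + N/S)
    expect_identical(g_closed > 0, lam > 2 * Ne * (1 + N / S))
  }
})

test_that("stationarity holds wherever the gain is interior", {
  ns <- noise_spec(0.5, 2)
  for (S in c(1, 5, 40)) {
    g <- optimal_gain(S, ns, 20)
    if (g > 0) {
      h <- 1e-6
      de <- (channel_objective(sqrt(g^2 + h), S, ns, 20) -
             channel_objective(sqrt(g^2 - h), S, ns, 20)) / (2 * h)
      expect_lt(abs(de), 1e-6)
    }
  }
})

test_that("gain profile is band-pass at high intensity and low-pass at low", {
  ns <- default_noise()
  corr <- analytic_correlation(n_channels = 120)
  S <- corr$eigenvalues
  g_hi <- gain_profile(S, ns, 10)
  expect_identical(classify_shape(as.numeric(g_hi)), "band-pass")
  expect_gt(attr(g_hi, "peak_index"), 1)
  expect_gte(attr(g_hi, "cutoff_index"), attr(g_hi, "peak_index"))

  g_lo <- gain_profile(1e-3 * S, ns, 10)
  expect_identical(classify_shape(as.numeric(g_lo)), "low-pass")
  expect_identical(attr(g_lo, "peak_index"), 1L)
  # monotone non-increasing over the active region
  act <- as.numeric(g_lo)[as.numeric(g_lo) > 0]
  expect_false(is.unsorted(rev(act)))

  expect_warning(gain_profile(rep(0, 5), ns, 10), "zero")
})

test_that("gain times root signal power is flat in the whitening limit", {
  ns <- default_noise()
  S <- 10^seq(5, 3, length.out = 30)    # all channels far above noise
  g <- as.numeric(gain_profile(S, ns, 10))
  w <- g^2 * S
  expect_lt(max(abs(w / mean(w) - 1)), 0.01)
  # spec'd normalization: g^2 S ~ (lambda - 2 Ne) / 2 at S >> N
  expect_lt(max(abs(w * 2 * (S + 1) / S / (10 - 2) - 1)), 0.05)
})

test_that("the total objective is minimized by the closed-form gain profile", {
  ns <- default_noise()
  ens <- make_spectral_ensemble(40, 400, seed = 17)
  corr <- estimate_correlation(ens)
  g_star <- as.numeric(gain_profile(corr$eigenvalues, ns, 10))
  sol <- total_objective(corr, g_star, ns, 10)
  expect_equal(sol$objective,
               sol$cost - 10 * sol$total_information * log(2),
               tolerance = 1e-10)

  zero <- total_objective(corr, rep(0, 40), ns, 10)
  expect_equal(zero$cost, 40 * ns$encoding_noise_var, tolerance = 1e-12)
  expect_equal(zero$total_information, 0)

  set.seed(71)
  for (i in 1:1000) {
    g_rand <- abs(g_star + rnorm(40, sd = 0.3)) *
      sample(c(0, 1), 40, replace = TRUE, prob = c(0.2, 0.8))
    e_rand <- total_objective(corr, g_rand, ns, 10)$objective
    expect_gte(e_rand, sol$objective - 1e-9 * abs(sol$objective))
  }
  expect_error(total_objective(corr, rep(1, 3), ns, 10), "length")
})

test_that("encode applies the transform with reproducible noise", {
  x <- matrix(rnorm(50 * 8), 50, 8)
  nolim <- list(input_noise_var = 0, encoding_noise_var = 0)
  expect_equal(encode(x, diag(8), nolim, seed = 1), x, tolerance = 1e-12)
  ns <- default_noise()
  o1 <- encode(x, diag(8), ns, seed = 4)
  o2 <- encode(x, diag(8), ns, seed = 4)
  expect_identical(o1, o2)
  expect_error(encode(x, diag(5), ns), "columns")
})

test_that("decorrelated gain-controlled outputs have the analytic covariance", {
  ens <- make_spectral_ensemble(30, 20000, intensity_scale = 5, seed = 23)
  corr <- analytic_correlation(ens)
  g <- as.numeric(gain_profile(corr$eigenvalues, default_noise(), 10))
  GU <- g * corr$eigenvectors
  nolim <- list(input_noise_var = 0, encoding_noise_var = 0)
  z <- encode(ens$samples, GU, nolim)
  emp <- crossprod(z) / nrow(z)
  ana <- diag(g^2 * corr$eigenvalues)
  expect_lt(max(abs(emp - ana)), 6 * max(ana) / sqrt(20000))
  # high-SNR whitened outputs are close to uncorrelated
  cc <- suppressWarnings(stats::cov2cor(emp[g > 0, g > 0]))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
})
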