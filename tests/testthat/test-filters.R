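test_that("SRF bank reduces to the identity under unit gains", {
  ens <- make_spectral_ensemble(25, 300, seed = 41)
  corr <- estimate_correlation(ens)
  bank <- build_srf(corr, rep(1, 25))
  expect_lt(max(abs(attr(bank, "K") - diag(25))), 1e-8)
  expect_error(build_srf(corr, rep(1, 7)), "length")
})

test_that("SRF output correlation follows the matrix identity", {
  ens <- make_spectral_ensemble(40, 300, seed = 42)
  corr <- estimate_correlation(ens)
  g <- as.numeric(gain_profile(corr$eigenvalues, default_noise(), 10))
  K <- attr(build_srf(corr, g), "K")
  lhs <- K %*% corr$R %*% t(K)
  U <- corr$eigenvectors
  rhs <- t(U) %*% (g * corr$eigenvalues * g * U)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("high-SNR SRFs are center-surround, sharper at low frequencies", {
  corr <- analytic_correlation(n_channels = 120)
  g <- as.numeric(gain_profile(corr$eigenvalues, default_noise(), 10))
  bank <- build_srf(corr, g)
  K <- attr(bank, "K")
  for (ch in c(30, 60, 90)) {
    row <- K[ch, ]
    expect_equal(which.max(row), ch)          # excitatory peak at own channel
    expect_lt(min(row), 0)                    # flanked by suppression
  }
  # low-frequency channels see higher SNR -> narrower excitatory core
  width <- function(ch) {
    row <- K[ch, ]
    sum(row >= max(row) / 2)
  }
  expect_lte(width(20), width(100))
})

test_that("acausal kernel from gains is even and magnitude-exact", {
  n <- 32
  omega <- ecstrf:::dft_frequencies(n)
  gains <- exp(-8 * abs(omega))
  f <- acausal_kernel_from_gains(gains)
  o <- f$origin_index
  for (tau in 1:(n / 2 - 1)) {
    expect_equal(f$coeffs[o + tau], f$coeffs[o - tau], tolerance = 1e-10)
  }
  expect_lt(max(abs(mag_fft(f$coeffs) - gains)), 1e-8)
  # flat gains give a discrete delta
  d <- acausal_kernel_from_gains(rep(2, 16))
  expect_equal(d$coeffs[d$origin_index], 2, tolerance = 1e-12)
  expect_lt(max(abs(d$coeffs[-d$origin_index])), 1e-12)
  expect_error(acausal_kernel_from_gains(c(1, 2, 3, 4)), "symmetric")
})

test_that("minimum phase reflects roots and preserves magnitude", {
  # already minimum phase: unchanged
  f1 <- minimum_phase(linear_filter(c(1, 0.5)))
  expect_equal(f1$coeffs, c(1, 0.5), tolerance = 1e-9)
  # single root at z = -2 reflected to -1/2
  f2 <- minimum_phase(linear_filter(c(0.5, 1)))
  expect_equal(f2$coeffs, c(1, 0.5), tolerance = 1e-9)
  expect_true(f2$causal)
  expect_error(minimum_phase(linear_filter(rep(0, 4))), "zero")

  set.seed(53)
  for (i in 1:20) {
    h <- rnorm(8)
    f <- minimum_phase(linear_filter(h))
    expect_lt(max(abs(mag_fft(f$coeffs, 64) - mag_fft(h, 64))),
              1e-6 * max(mag_fft(h, 64)))
    # zeros of the transfer function inside the closed unit disk, i.e.
    # all roots of the polynomial in z^-1 on or outside the unit circle
    r <- ecstrf:::polynomial_roots(f$coeffs)
    expect_true(all(Mod(r) >= 1 - 1e-6))
    # idempotence
    f2 <- minimum_phase(f)
    expect_equal(f2$coeffs[seq_along(f$coeffs)], f$coeffs,
                 tolerance = 1e-9)
  }
})

test_that("minimum phase maximizes partial energy among root-reflection alternatives", {
  # brute force: reflecting any conjugate-closed subset of roots gives a
  # magnitude-equivalent real causal filter; the minimum-phase one must
  # dominate the cumulative energy sums at every lag
  reconstruct <- function(lead, roots) {
    p <- as.complex(lead)
    for (r in roots) p <- c(0i, p) - r * c(p, 0i)
    Re(p)
  }
  set.seed(57)
  for (trial in 1:8) {
    h <- rnorm(sample(6:8, 1))
    f <- minimum_phase(linear_filter(h))
    cum_min <- cumsum(f$coeffs^2)
    roots <- ecstrf:::polynomial_roots(h)
    # conjugate-closed units: real roots alone, conjugate pairs together
    units <- list()
    used <- rep(FALSE, length(roots))
    for (j in seq_along(roots)) {
      if (used[j]) next
      if (abs(Im(roots[j])) < 1e-9 * (1 + Mod(roots[j]))) {
        units[[length(units) + 1L]] <- j
        used[j] <- TRUE
      } else {
        mate <- which(!used & abs(roots - Conj(roots[j])) <
                        1e-6 * (1 + Mod(roots[j])))
        mate <- setdiff(mate, j)[1]
        units[[length(units) + 1L]] <- c(j, mate)
        used[c(j, mate)] <- TRUE
      }
    }
    nmag <- max(mag_fft(h, 64))
    for (mask in 0:(2^length(units) - 1)) {
      alt <- roots
      scale <- 1
      for (u in seq_along(units)) {
        if (bitwAnd(mask, 2^(u - 1)) > 0) {
          for (j in units[[u]]) {
            scale <- scale * Mod(alt[j])
            alt[j] <- 1 / Conj(alt[j])
          }
        }
      }
      halt <- reconstruct(h[length(h)], alt) * scale
      # every alternative shares the magnitude response
      expect_lt(max(abs(mag_fft(halt, 64) - mag_fft(h, 64))), 1e-6 * nmag)
      cum_alt <- cumsum(halt^2)
      expect_true(all(cum_min + 1e-7 * max(cum_min) >=
                        cum_alt[seq_along(cum_min)]))
    }
  }
})

test_that("TRF is causal with the gain profile as its magnitude response", {
  ns <- default_noise()
  corr <- analytic_correlation(n_channels = 64, intensity_scale = 10,
                               smoothing_length = 5, circular = TRUE)
  S <- fourier_decorrelate(corr$R[1, ])
  trf <- build_trf(S, ns, 6)
  g <- attr(trf, "gains")
  expect_true(trf$causal)
  expect_lt(max(abs(mag_fft(trf$coeffs, 64) - g)), 1e-6 * max(g))
  # high SNR: band-pass MTF, alternating-sign lobes
  lm <- lobe_metrics(trf)
  expect_gt(lm$n_inhibitory_lobes, 0)
  expect_identical(peak_and_cutoff(mtf_of(trf))$shape_class, "band-pass")

  # low SNR: one dominant excitatory bump, at most weak residual inhibition
  corr_lo <- analytic_correlation(n_channels = 64, intensity_scale = 0.3,
                                  smoothing_length = 5, circular = TRUE)
  trf_lo <- build_trf(fourier_decorrelate(corr_lo$R[1, ]), ns, 6)
  lm_lo <- lobe_metrics(trf_lo)
  expect_identical(lm_lo$n_excitatory_lobes, 1L)
  expect_lt(lm_lo$inhibitory_strength_ratio, 0.2)
  expect_identical(peak_and_cutoff(mtf_of(trf_lo))$shape_class, "low-pass")
})

test_that("STRF is strictly causal and matches its generating gains", {
  ns <- default_noise()
  mp <- modulation_power_2d(test_omega_f(), test_omega_t(),
                            corr_f = 3, corr_t = 0.1, scale = 10)
  strf <- build_strf(mp, ns, 10)
  g <- attr(strf, "gains")
  expect_true(strf$causal)
  expect_identical(ncol(strf$kernel), 64L)    # latencies 0..63 only: no
                                              # negative-latency taps exist
  M <- Mod(ecstrf:::apply_fft2(strf$kernel))
  supp <- g > 0
  expect_lt(max(abs(M[supp] - g[supp]) / g[supp]), 0.02)
})

test_that("STRF lobes simplify and widen as SNR drops, latency shortens as it rises", {
  ns <- default_noise()
  of <- test_omega_f()
  ot <- test_omega_t()
  build <- function(scale) {
    build_strf(modulation_power_2d(of, ot, corr_f = 3, corr_t = 0.1,
                                   scale = scale), ns, 6)
  }
  hi <- build(10)
  lo <- build(0.1)
  row_hi <- lobe_metrics(hi$kernel[hi$origin_row, ], axis_step = hi$time_step)
  row_lo <- lobe_metrics(lo$kernel[lo$origin_row, ], axis_step = lo$time_step)
  expect_lte(row_lo$n_excitatory_lobes + row_lo$n_inhibitory_lobes,
             row_hi$n_excitatory_lobes + row_hi$n_inhibitory_lobes)
  expect_gte(row_lo$main_lobe_width, row_hi$main_lobe_width)
  expect_lte(row_lo$inhibitory_strength_ratio,
             row_hi$inhibitory_strength_ratio)

  # peak latency non-increasing across an SNR ladder
  lat <- vapply(c(0.1, 1, 10), function(sc) {
    k <- build(sc)$kernel
    which.max(apply(abs(k), 2, max))
  }, numeric(1))
  expect_false(is.unsorted(rev(lat)))
})

test_that("STRF convolution obeys the impulse and matched-stimulus identities", {
  ns <- default_noise()
  mp <- modulation_power_2d(test_omega_f(), test_omega_t(),
                            corr_f = 3, corr_t = 0.1, scale = 10)
  strf <- build_strf(mp, ns, 6, f0 = 2)
  n_ch <- 40
  n_fr <- 150
  fax <- 2 + (seq_len(n_ch) - 20) * strf$freq_step
  tax <- (seq_len(n_fr) - 1) * strf$time_step
  spec <- list(power = matrix(0, n_ch, n_fr), freq_axis = fax,
               time_axis = tax)

  # all-zero spectrogram -> all-zero response
  expect_true(all(apply_strf(spec, strf) == 0))

  # impulse at (f0, t*) -> the kernel's f0 row starting at t*
  tstar <- 30
  spec$power[20, tstar] <- 1
  r <- apply_strf(spec, strf)
  expect_equal(r[tstar:(tstar + 20)], strf$kernel[strf$origin_row, 1:21],
               tolerance = 1e-10)

  # stimulus matching the time-reversed kernel peaks the response at t0
  t0 <- 100
  spec$power[] <- 0
  for (d in seq_len(nrow(strf$kernel))) {
    ch <- 20 + (d - strf$origin_row)
    taps <- strf$kernel[d, ]
    cols <- t0 - (seq_along(taps) - 1)
    ok <- cols >= 1
    spec$power[ch, cols[ok]] <- taps[ok]
  }
  r2 <- apply_strf(spec, strf)
  expect_identical(which.max(r2), as.integer(t0))

  bad <- spec
  bad$time_axis <- tax * 2
  expect_error(apply_strf(bad, strf), "time step")
})
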