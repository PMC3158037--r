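# Shared fixtures and independent oracles.

default_noise <- function() noise_spec(1, 1)

# Independent numeric minimizer of the per-channel objective (golden-section
# via optimize over a bracket that always contains the optimum).
numeric_optimal_gain <- function(S, N, Ne, tradeoff) {
  ns <- noise_spec(N, Ne)
  f <- function(g) channel_objective(g, S, ns, tradeoff)
  upper <- sqrt(tradeoff / (2 * max(S + N, 1e-12))) + 10
  opt <- stats::optimize(f, c(0, upper), tol = 1e-12)
  boundary <- f(0) <= opt$objective + 1e-10 * (1 + abs(f(0)))
  if (boundary || opt$minimum < 1e-7) 0 else opt$minimum
}

# DFT-order magnitude of a causal tap vector on an n-point grid.
mag_fft <- function(taps, n = length(taps)) {
  Mod(stats::fft(c(taps, rep(0, n - length(taps)))))
}

# Reference modulation grids used across 2-D tests (the package defaults).
test_omega_f <- function() ecstrf:::dft_frequencies(32, 0.125)
test_omega_t <- function() ecstrf:::dft_frequencies(64, 0.003)

# Reproducible Gaussian matrix (for random orthonormal transforms).
with_seed_matrix <- function(seed, n) {
  ecstrf:::with_seed(seed, matrix(stats::rnorm(n * n), n, n))
}

gain_mtf <- function(g, omega_f, omega_t) {
  structure(list(magnitude = g, omega_f = omega_f, omega_t = omega_t,
                 normalization = "gain"),
            class = "mtf")
}
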