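#' Correlation model: input correlation matrix and its principal axes
#'
#' Wraps a symmetric input correlation matrix `R` together with its
#' eigendecomposition. Row `k` of `$eigenvectors` is the k-th principal axis
#' (the decorrelating transform `U`), and `$eigenvalues[k]` is the signal
#' power `S_k` of the k-th decorrelated channel. Conventions, fixed so that
#' derived filters are reproducible:
#' eigenvalues are sorted descending and clipped at zero (small sampling-noise
#' negatives only); each eigenvector's first non-negligible component is made
#' positive; within a numerically degenerate eigenvalue block, eigenvectors
#' are ordered by ascending zero-crossing count, mirroring the monotone
#' relation between channel index and modulation frequency.
#'
#' @param R symmetric real matrix.
#' @param translation_invariant flag: correlation depends on lag only.
#' @param power_spectrum optional S(omega) array for translation-invariant
#'   models.
#' @return a `correlation_model` with fields `R`, `eigenvalues`,
#'   `eigenvectors` (rows = principal axes), `translation_invariant`,
#'   `power_spectrum`.
#' @export
correlation_model <- function(R, translation_invariant = FALSE,
                              power_spectrum = NULL) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8 * max(abs(R), 1e-300)) {
    stop_param("R must be a symmetric square matrix")
  }
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- eg$values
  mx <- max(abs(vals), 1e-300)
  if (min(vals) < -1e-8 * mx) {
    warning("correlation matrix has eigenvalues well below zero; clipping")
  }
  vals <- pmax(vals, 0)
  U <- t(eg$vectors)                       # rows are principal axes

  # fix sign: first component with non-negligible magnitude made positive
  for (k in seq_len(nrow(U))) {
    v <- U[k, ]
    j <- which(abs(v) > 1e-8 * max(abs(v)))[1]
    if (v[j] < 0) U[k, ] <- -v
  }

  # order degenerate blocks by ascending zero-crossing count
  blocks <- split(seq_along(vals),
                  cumsum(c(1, abs(diff(vals)) > 1e-8 * mx)))
  for (b in blocks) {
    if (length(b) > 1L) {
      zc <- vapply(b, function(k) zero_crossings(U[k, ]), integer(1))
      U[b, ] <- U[b[order(zc)], ]
    }
  }

  structure(
    list(R = R,
         eigenvalues = vals,
         eigenvectors = U,
         translation_invariant = translation_invariant,
         power_spectrum = power_spectrum),
    class = "correlation_model"
  )
}

zero_crossings <- function(v) {
  s <- sign(v[abs(v) > 1e-8 * max(abs(v), 1e-300)])
  sum(s[-1] * s[-length(s)] < 0)
}

#' Empirical correlation of an ensemble
#'
#' Sample second-moment matrix `R[a, b] = mean(x_a * x_b)` of an ensemble's
#' samples (the generator is zero-mean by construction; no mean is
#' re-subtracted), with the eigendecomposition attached.
#'
#' @param ensemble a `spectral_ensemble`, or a plain samples matrix
#'   (`n_samples x n_channels`).
#' @return a [correlation_model()].
#' @export
estimate_correlation <- function(ensemble) {
  x <- if (inherits(ensemble, "spectral_ensemble")) ensemble$samples
       else as.matrix(ensemble)
  if (nrow(x) < 2L) {
    stop_param("need at least 2 samples to estimate a correlation matrix")
  }
  ti <- inherits(ensemble, "spectral_ensemble") && isTRUE(ensemble$circular)
  correlation_model(crossprod(x) / nrow(x), translation_invariant = ti)
}

#' Decorrelate a translation-invariant ensemble by Fourier transform
#'
#' For correlations that depend on lag only, the decorrelating transform is
#' the (1-D or 2-D) DFT and the channel signal powers are the DFT of the lag
#' correlation function. Small negative values from discretization are
#' clipped at zero with a warning.
#'
#' @param lag_correlation real vector (or matrix) of correlations indexed by
#'   circular lag, starting at lag 0 in standard DFT order.
#' @param tol symmetry tolerance, relative to the maximum.
#' @return power spectrum S(omega) in standard DFT order, with the
#'   frequency grid (cycles per lag unit) as attribute `"frequencies"`
#'   (1-D case).
#' @export
fourier_decorrelate <- function(lag_correlation, tol = 1e-6) {
  r <- lag_correlation
  mx <- max(abs(r), 1e-300)
  if (is.matrix(r)) {
    flipped <- r[c(1L, rev(seq_len(nrow(r))[-1L])),
                 c(1L, rev(seq_len(ncol(r))[-1L]))]
    if (max(abs(r - flipped)) > tol * mx) {
      stop_param("lag correlation is not symmetric under lag negation")
    }
    S <- Re(apply_fft2(r))
  } else {
    flipped <- r[c(1L, rev(seq_along(r)[-1L]))]
    if (max(abs(r - flipped)) > tol * mx) {
      stop_param("lag correlation is not symmetric under lag negation")
    }
    S <- Re(stats::fft(r))
  }
  neg <- min(S)
  if (neg < -tol * max(abs(S), 1e-300)) {
    warning(sprintf("power spectrum has negative values (min %.3g); clipping",
                    neg))
  }
  S <- pmax(S, 0)
  if (!is.matrix(r)) {
    attr(S, "frequencies") <- dft_frequencies(length(r))
  }
  S
}

apply_fft2 <- function(m) {
  stats::mvfft(t(stats::mvfft(t(m))))
}

#' Channel noise specification
#'
#' IID Gaussian noise variances: `input_noise_var` (N) corrupts each input
#' channel before encoding; `encoding_noise_var` (N_e) is added to each
#' output channel by the encoding itself.
#' @param input_noise_var,encoding_noise_var strictly positive variances.
#' @export
noise_spec <- function(input_noise_var = 1, encoding_noise_var = 1) {
  check_positive(input_noise_var, "input_noise_var")
  check_positive(encoding_noise_var, "encoding_noise_var")
  structure(list(input_noise_var = input_noise_var,
                 encoding_noise_var = encoding_noise_var),
            class = "noise_spec")
}

as_noise_spec <- function(noise) {
  if (inherits(noise, "noise_spec")) return(noise)
  if (is.list(noise)) {
    return(noise_spec(noise$input_noise_var, noise$encoding_noise_var))
  }
  stop_param("`noise` must be a noise_spec")
}

#' Information transmitted by one gain-controlled channel
#'
#' For a decorrelated Gaussian channel with signal power `S`, input noise
#' variance `N`, encoding noise variance `N_e` and gain `g`, the output
#' `O = g (s + n) + n_e` carries
#' `I = 1/2 log2[(g^2 (S + N) + N_e) / (g^2 N + N_e)]` bits about the signal.
#'
#' @param g nonnegative gain (vectorized).
#' @param S nonnegative signal power (vectorized).
#' @param noise a [noise_spec()].
#' @return information in bits.
#' @export
channel_information <- function(g, S, noise) {
  noise <- as_noise_spec(noise)
  N <- noise$input_noise_var
  Ne <- noise$encoding_noise_var
  0.5 * log2((g^2 * (S + N) + Ne) / (g^2 * N + Ne))
}

#' Per-channel efficient-coding objective
#'
#' `e(g) = [g^2 (S + N) + N_e] - lambda * I_nats(g)`: output power (the
#' neural cost of the channel) minus `tradeoff` times the transmitted
#' information. Information enters in nats (factor `lambda/2` in front of a
#' natural log), which keeps the stationarity algebra clean; reported
#' information elsewhere is in bits (1 bit = `log(2)` nats).
#'
#' @inheritParams channel_information
#' @param tradeoff positive information-cost tradeoff (lambda).
#' @return objective value (cost units).
#' @export
channel_objective <- function(g, S, noise, tradeoff) {
  noise <- as_noise_spec(noise)
  check_positive(tradeoff, "tradeoff")
  N <- noise$input_noise_var
  Ne <- noise$encoding_noise_var
  g^2 * (S + N) + Ne -
    tradeoff * 0.5 * log((g^2 * (S + N) + Ne) / (g^2 * N + Ne))
}

#' Optimal gain of a decorrelated channel
#'
#' Closed-form minimizer of [channel_objective()]:
#' `g*^2 = max{0, N_e / (2 N (S + N)) * [sqrt(S^2 + 2 lambda N S / N_e) -
#' (S + 2 N)]}`. The gain is exactly zero below the soft threshold
#' `tradeoff <= 2 N_e (1 + N / S)`: channels whose signal-to-noise ratio is
#' too poor to be worth the coding cost are shut off rather than amplified.
#'
#' @param S nonnegative signal power (vectorized).
#' @param noise a [noise_spec()].
#' @param tradeoff positive tradeoff lambda.
#' @return nonnegative optimal gain(s), same shape as `S`.
#' @export
optimal_gain <- function(S, noise, tradeoff) {
  noise <- as_noise_spec(noise)
  check_positive(tradeoff, "tradeoff")
  if (any(S < 0)) stop_param("signal powers must be nonnegative")
  N <- noise$input_noise_var
  Ne <- noise$encoding_noise_var
  g2 <- Ne / (2 * N * (S + N)) *
    (sqrt(S^2 + 2 * tradeoff * N * S / Ne) - (S + 2 * N))
  g2 <- pmax(g2, 0)
  out <- sqrt(g2)
  attributes(out) <- attributes(S)
  out
}

#' Optimal gain profile across decorrelated channels
#'
#' Elementwise [optimal_gain()] over a vector of signal powers `S_k`
#' (descending, as eigenvalues) or a 2-D modulation power array. For a
#' vector profile the result carries `peak_index` (k0, argmax of the gain;
#' ties resolved toward the lowest index) and `cutoff_index` (k_c, the
#' largest channel with strictly positive gain — the closed form reaches
#' zero exactly). For a [modulation_power_2d()] object the gains inherit the
#' modulation grid and the peak/cutoff indices are reported per axis on the
#' nonnegative-frequency quadrant.
#'
#' @param powers numeric vector, matrix, or `modulation_power` object.
#' @inheritParams optimal_gain
#' @return gains of matching shape with attributes `peak_index` and
#'   `cutoff_index` (vector case), or a `modulation_power`-like object with
#'   `$gain` (2-D case).
#' @export
gain_profile <- function(powers, noise, tradeoff) {
  if (inherits(powers, "modulation_power")) {
    g <- optimal_gain(powers$power, noise, tradeoff)
    if (all(g == 0)) warning("all gains are zero (SNR below threshold)")
    out <- powers
    out$gain <- g
    class(out) <- c("gain_profile_2d", "modulation_power")
    return(out)
  }
  g <- optimal_gain(powers, noise, tradeoff)
  if (all(g == 0)) warning("all gains are zero (SNR below threshold)")
  if (is.null(dim(g))) {
    attr(g, "peak_index") <- which.max(g)
    attr(g, "cutoff_index") <- if (any(g > 0)) max(which(g > 0)) else 0L
  }
  g
}

#' Total efficient-coding objective over all channels
#'
#' Sums cost, information and objective over the decorrelated channels of a
#' correlation model: `cost = sum(g_k^2 (S_k + N) + N_e)` (total output
#' power), `total_information = sum(I_k)` in bits, and
#' `objective = cost - tradeoff * total_information_nats`.
#'
#' @param correlation a [correlation_model()].
#' @param gains nonnegative vector matching the eigenvalue count.
#' @param noise a [noise_spec()].
#' @param tradeoff positive tradeoff lambda.
#' @return a `coding_solution`: gains, per-channel information (bits),
#'   output power, cost, total information (bits), objective, tradeoff,
#'   noise.
#' @export
total_objective <- function(correlation, gains, noise, tradeoff) {
  stopifnot(inherits(correlation, "correlation_model"))
  noise <- as_noise_spec(noise)
  check_positive(tradeoff, "tradeoff")
  S <- correlation$eigenvalues
  if (length(gains) != length(S)) {
    stop_param("`gains` length must match the number of eigenvalues")
  }
  N <- noise$input_noise_var
  Ne <- noise$encoding_noise_var
  output_power <- gains^2 * (S + N) + Ne
  info_bits <- channel_information(gains, S, noise)
  cost <- sum(output_power)
  total_bits <- sum(info_bits)
  structure(
    list(gains = as.numeric(gains),
         information = info_bits,
         output_power = output_power,
         cost = cost,
         total_information = total_bits,
         objective = cost - tradeoff * total_bits * log(2),
         tradeoff = tradeoff,
         noise = noise),
    class = "coding_solution"
  )
}

#' Encode samples through a linear transform with noise
#'
#' `O = K (x + n) + n_e` with iid Gaussian input noise `n` and encoding
#' noise `n_e` drawn fresh per sample; deterministic for a fixed seed.
#' Zero noise variances are accepted here (noiseless limit for testing).
#'
#' @param samples matrix (`n_samples x n_inputs`).
#' @param K encoding matrix (`n_outputs x n_inputs`).
#' @param noise a [noise_spec()], or a list with possibly zero variances.
#' @param seed integer seed for the noise draws.
#' @return matrix (`n_samples x n_outputs`) of encoded outputs.
#' @export
encode <- function(samples, K, noise, seed = 1L) {
  x <- as.matrix(samples)
  K <- as.matrix(K)
  if (ncol(K) != ncol(x)) {
    stop_param("K columns must match the sample dimension")
  }
  N <- noise$input_noise_var
  Ne <- noise$encoding_noise_var
  check_nonnegative(N, "input_noise_var")
  check_nonnegative(Ne, "encoding_noise_var")
  with_seed(seed, {
    n_in <- if (N > 0) {
      matrix(stats::rnorm(length(x), sd = sqrt(N)), nrow(x), ncol(x))
    } else 0
    out <- (x + n_in) %*% t(K)
    if (Ne > 0) {
      out <- out + matrix(stats::rnorm(length(out), sd = sqrt(Ne)),
                          nrow(out), ncol(out))
    }
    out
  })
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf(
    "<correlation_model> %d channels, eigenvalues [%.4g .. %.4g]%s\n",
    nrow(x$R), max(x$eigenvalues), min(x$eigenvalues),
    if (x$translation_invariant) ", translation invariant" else ""))
  invisible(x)
}

#' @export
print.coding_solution <- function(x, ...) {
  cat(sprintf(
    "<coding_solution> %d channels: cost %.4g, information %.4g bits, objective %.4g (tradeoff %.3g)\n",
    length(x$gains), x$cost, x$total_information, x$objective, x$tradeoff))
  cat(sprintf("  active channels: %d of %d\n",
              sum(x$gains > 0), length(x$gains)))
  invisible(x)
}
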