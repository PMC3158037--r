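#' 1-D linear filter kernel
#'
#' Container for a spectral or temporal filter: `coeffs` over discrete lags
#' (or frequency offsets), the tap spacing `axis_step` (seconds or octaves),
#' a causality flag, and `origin_index`, the tap holding zero lag.
#'
#' @param coeffs real coefficient vector.
#' @param axis_step spacing between taps.
#' @param causal logical; if `TRUE`, taps before `origin_index` must vanish.
#' @param origin_index index of the zero-lag tap.
#' @export
linear_filter <- function(coeffs, axis_step = 1, causal = FALSE,
                          origin_index = 1L) {
  coeffs <- as.numeric(coeffs)
  if (any(!is.finite(coeffs))) stop_param("filter coefficients must be finite")
  check_positive(axis_step, "axis_step")
  origin_index <- check_count(origin_index, "origin_index")
  if (causal && origin_index > 1L &&
      any(abs(coeffs[seq_len(origin_index - 1L)]) > 0)) {
    stop_param("causal filter has nonzero taps at negative lags")
  }
  structure(list(coeffs = coeffs, axis_step = axis_step, causal = causal,
                 origin_index = origin_index),
            class = "linear_filter")
}

#' Spectral receptive field bank
#'
#' Assembles the full encoding matrix `K = U' G U` from a correlation model
#' (rows of `U` are the principal axes) and a gain vector, taking the
#' multiplexing transform to be `U'` — the choice that localizes each
#' receptive field around its own channel. Row `j` of `K` is the spectral
#' receptive field (SRF) of output neuron `j`; `K` is symmetric for real
#' inputs.
#'
#' @param correlation a [correlation_model()].
#' @param gains nonnegative vector, one gain per decorrelated channel.
#' @param axis_step channel spacing in octaves.
#' @return an `srf_bank`: a list of [linear_filter()] objects (one per
#'   output channel, `origin_index` at the channel itself) with the full
#'   matrix in `attr(, "K")`.
#' @export
build_srf <- function(correlation, gains, axis_step = 1) {
  stopifnot(inherits(correlation, "correlation_model"))
  U <- correlation$eigenvectors
  if (length(gains) != nrow(U)) {
    stop_param("`gains` length must match the number of principal axes")
  }
  K <- crossprod(U, gains * U)        # U' G U
  K <- (K + t(K)) / 2
  bank <- lapply(seq_len(nrow(K)), function(j) {
    linear_filter(K[j, ], axis_step = axis_step, causal = FALSE,
                  origin_index = j)
  })
  attr(bank, "K") <- K
  class(bank) <- "srf_bank"
  bank
}

#' @export
print.srf_bank <- function(x, ...) {
  K <- attr(x, "K")
  cat(sprintf("<srf_bank> %d receptive fields of %d taps\n",
              nrow(K), ncol(K)))
  invisible(x)
}

#' Even acausal kernel from a symmetric gain profile
#'
#' Inverse DFT of a real gain-magnitude profile given in standard DFT order.
#' With zero phase the result is a real, even, acausal kernel centred on the
#' zero-lag tap; its DFT magnitude reproduces the input gains exactly.
#'
#' @param gains nonnegative vector in standard DFT order, symmetric under
#'   frequency negation (`gains[k] == gains[n - k + 2]`).
#' @param axis_step tap spacing.
#' @param tol symmetry tolerance relative to the maximum gain.
#' @return an acausal [linear_filter()] with `origin_index` at the centre.
#' @export
acausal_kernel_from_gains <- function(gains, axis_step = 1, tol = 1e-8) {
  g <- as.numeric(gains)
  n <- length(g)
  if (n < 2L) stop_param("need at least 2 gain samples")
  mirrored <- g[c(1L, rev(seq_len(n)[-1L]))]
  if (max(abs(g - mirrored)) > tol * max(abs(g), 1e-300)) {
    stop_param("gains must be symmetric in +/- frequency")
  }
  kern <- Re(stats::fft(g, inverse = TRUE)) / n
  idx <- fftshift_index(n)
  linear_filter(kern[idx], axis_step = axis_step, causal = FALSE,
                origin_index = floor(n / 2) + 1L)
}

# Roots of the polynomial c[1] + c[2] x + ... + c[m+1] x^m via eigenvalues
# of the companion matrix (taps below 1e-12 of the maximum are trimmed by
# the caller).
polynomial_roots <- function(coeffs) {
  m <- length(coeffs) - 1L
  if (m < 1L) return(complex(0))
  C <- matrix(0, m, m)
  if (m > 1L) C[cbind(2:m, 1:(m - 1L))] <- 1
  C[, m] <- -coeffs[1:m] / coeffs[m + 1L]
  eigen(C, only.values = TRUE)$values
}

#' Causal minimum-phase counterpart of a filter
#'
#' Three-step causalization: (1) shift the finitely supported taps to causal
#' positions; (2) find the complex roots of the tap polynomial (companion
#' matrix eigenvalues); (3) reflect every root of the polynomial in
#' `z^{-1}` lying inside the unit circle to its conjugate reciprocal
#' (equivalently: every zero of the transfer function outside the unit
#' circle is reflected inside) and rescale so the magnitude response is
#' preserved. Among all causal filters sharing the input's magnitude
#' response, the result concentrates energy maximally at early lags. Roots
#' within `1e-8` of the unit circle are left in place. The overall sign is
#' fixed so the largest-magnitude tap is positive.
#'
#' @param filter a [linear_filter()] (or bare numeric vector of taps).
#' @return a causal minimum-phase [linear_filter()] with the same magnitude
#'   response.
#' @export
minimum_phase <- function(filter) {
  if (is.numeric(filter)) filter <- linear_filter(filter)
  stopifnot(inherits(filter, "linear_filter"))
  h <- filter$coeffs
  mx <- max(abs(h))
  if (mx == 0) stop_param("cannot causalize an all-zero filter")
  nz <- which(abs(h) > 1e-12 * mx)
  h <- h[nz[1]:nz[length(nz)]]

  if (length(h) == 1L) {
    return(linear_filter(abs(h), axis_step = filter$axis_step,
                         causal = TRUE, origin_index = 1L))
  }

  roots <- polynomial_roots(h)
  if (any(!is.finite(roots))) {
    stop_param("root finding failed for the tap polynomial")
  }
  inside <- Mod(roots) < 1 - 1e-8
  scale_mag <- prod(Mod(roots[inside]))
  roots[inside] <- 1 / Conj(roots[inside])

  # rebuild ascending real coefficients from the leading coefficient and the
  # roots: real roots give linear factors, conjugate pairs real quadratics
  # (eigenvalues of a real companion matrix come in exact conjugate pairs)
  p <- h[length(h)]
  for (r in roots[Im(roots) == 0 |
                  abs(Im(roots)) <= 1e-12 * (1 + Mod(roots))]) {
    p <- c(0, p) - Re(r) * c(p, 0)
  }
  for (r in roots[Im(roots) > 1e-12 * (1 + Mod(roots))]) {
    p <- c(0, 0, p) - 2 * Re(r) * c(0, p, 0) + Mod(r)^2 * c(p, 0, 0)
  }
  hmin <- p * scale_mag
  if (length(hmin) != length(h)) {
    stop_param("root reflection produced a non-real filter; root finding failed")
  }

  # residual magnitude correction against numerical drift in reconstruction
  nfft <- max(256L, 2L * length(h))
  Fin <- Mod(stats::fft(c(h, rep(0, nfft - length(h)))))
  Fout <- Mod(stats::fft(c(hmin, rep(0, nfft - length(hmin)))))
  use <- Fin > 1e-8 * max(Fin) & Fout > 0
  if (any(use)) hmin <- hmin * stats::median(Fin[use] / Fout[use])
  if (hmin[which.max(abs(hmin))] < 0) hmin <- -hmin

  linear_filter(hmin, axis_step = filter$axis_step, causal = TRUE,
                origin_index = 1L)
}

#' Causal temporal receptive field from a power spectrum
#'
#' The TRF pipeline for a translation-invariant temporal ensemble: optimal
#' gains over temporal modulation frequency ([optimal_gain()]), zero-phase
#' inverse DFT to an even acausal kernel ([acausal_kernel_from_gains()]),
#' then minimum-phase causalization ([minimum_phase()]). The causal result
#' retains the gain profile as its DFT magnitude.
#'
#' @param power_spectrum nonnegative signal power S(omega) in standard DFT
#'   order, symmetric under frequency negation.
#' @param noise a [noise_spec()].
#' @param tradeoff positive tradeoff lambda.
#' @param axis_step seconds per tap.
#' @return a causal [linear_filter()]; the generating gain profile is kept
#'   in `attr(, "gains")`.
#' @export
build_trf <- function(power_spectrum, noise, tradeoff, axis_step = 1) {
  S <- as.numeric(power_spectrum)
  if (any(S < 0)) stop_param("power spectrum must be nonnegative")
  g <- gain_profile(S, noise, tradeoff)
  trf <- minimum_phase(
    acausal_kernel_from_gains(as.numeric(g), axis_step = axis_step))
  if (length(trf$coeffs) < length(S)) {
    trf$coeffs <- c(trf$coeffs, rep(0, length(S) - length(trf$coeffs)))
  }
  attr(trf, "gains") <- as.numeric(g)
  trf
}

#' 2-D spectro-temporal receptive field kernel
#'
#' Container for an STRF: `kernel[frequency offset, latency]` with the
#' frequency-offset axis centred on the neuron's preferred frequency `f0`
#' and the latency axis starting at zero (causal).
#'
#' @param kernel real matrix, rows = frequency offsets, columns = latency.
#' @param freq_step octaves per row.
#' @param time_step seconds per column.
#' @param f0 preferred (centre) frequency in octaves.
#' @param causal logical causality flag.
#' @param origin_row row index of zero frequency offset.
#' @export
strf_kernel <- function(kernel, freq_step, time_step, f0 = 0,
                        causal = TRUE, origin_row = floor(nrow(kernel) / 2) + 1L) {
  kernel <- as.matrix(kernel)
  if (any(!is.finite(kernel))) stop_param("kernel must be finite")
  check_positive(freq_step, "freq_step")
  check_positive(time_step, "time_step")
  structure(list(kernel = kernel, freq_step = freq_step,
                 time_step = time_step, f0 = f0, causal = causal,
                 origin_row = origin_row),
            class = "strf_kernel")
}

#' @export
print.strf_kernel <- function(x, ...) {
  cat(sprintf(
    "<strf_kernel> %d freq offsets x %d latencies (%.3g oct, %.3g s steps), f0 = %.3g oct%s\n",
    nrow(x$kernel), ncol(x$kernel), x$freq_step, x$time_step, x$f0,
    if (x$causal) ", causal" else ""))
  invisible(x)
}

#' Causal 2-D STRF from a modulation power spectrum
#'
#' Extends the TRF construction to two dimensions. For each spectral
#' modulation frequency `omega_f`, the temporal gain slice
#' `g(omega_f, .)` is inverse-DFT'd to an even acausal temporal filter and
#' causalized by [minimum_phase()] (per-slice causalization preserves each
#' slice's temporal magnitude response); the causal slices are then
#' inverse-DFT'd across `omega_f` to produce `STRF(f - f0, t)`. The kernel
#' is strictly zero for negative latency by construction, and the magnitude
#' of its 2-D DFT reproduces the generating gain profile.
#'
#' @param mod_power a [modulation_power_2d()] object (DFT-ordered uniform
#'   grids).
#' @param noise a [noise_spec()].
#' @param tradeoff positive tradeoff lambda.
#' @param f0 preferred frequency in octaves.
#' @return a causal [strf_kernel()]; the 2-D gain profile is kept in
#'   `attr(, "gains")`.
#' @export
build_strf <- function(mod_power, noise, tradeoff, f0 = 0) {
  stopifnot(inherits(mod_power, "modulation_power"))
  g <- optimal_gain(mod_power$power, noise, tradeoff)
  if (all(g == 0)) stop_param("all gains are zero (SNR below threshold)")
  n_f <- nrow(g)
  n_t <- ncol(g)
  d_of <- abs(mod_power$omega_f[2] - mod_power$omega_f[1])
  d_ot <- abs(mod_power$omega_t[2] - mod_power$omega_t[1])
  freq_step <- 1 / (n_f * d_of)
  time_step <- 1 / (n_t * d_ot)

  H <- matrix(0, n_f, n_t)
  for (i in seq_len(n_f)) {
    gi <- g[i, ]
    if (all(gi == 0)) next
    hi <- minimum_phase(acausal_kernel_from_gains(gi, axis_step = time_step))
    H[i, seq_along(hi$coeffs)] <- hi$coeffs
  }

  kernel <- Re(stats::mvfft(H + 0i, inverse = TRUE)) / n_f
  kernel <- kernel[fftshift_index(n_f), , drop = FALSE]
  out <- strf_kernel(kernel, freq_step = freq_step, time_step = time_step,
                     f0 = f0, causal = TRUE,
                     origin_row = floor(n_f / 2) + 1L)
  attr(out, "gains") <- g
  out
}

#' Convolve a spectrogram with an STRF
#'
#' Linear response `r(t) = sum_f sum_{t' >= 0} STRF(f, t') S(f, t - t')`.
#' The kernel's frequency-offset rows are aligned to the spectrogram channel
#' nearest `f0`; rows falling outside the spectrogram are treated as zero
#' input, and the spectrogram history before its first frame is zero-padded.
#'
#' @param spectrogram a [spectrogram_from_waveform()] result, or any list
#'   with `power` (channels x frames), `freq_axis`, `time_axis`.
#' @param kernel a causal [strf_kernel()].
#' @return numeric response time series, one value per spectrogram frame.
#' @export
apply_strf <- function(spectrogram, kernel) {
  stopifnot(inherits(kernel, "strf_kernel"))
  S <- spectrogram$power
  fax <- spectrogram$freq_axis
  tax <- spectrogram$time_axis
  if (length(tax) > 1) {
    dt <- tax[2] - tax[1]
    if (abs(dt - kernel$time_step) > 1e-6 * kernel$time_step) {
      stop_param("spectrogram frame step does not match the kernel time step")
    }
  }
  if (length(fax) > 1) {
    df <- fax[2] - fax[1]
    if (abs(df - kernel$freq_step) > 1e-6 * kernel$freq_step) {
      stop_param("spectrogram channel step does not match the kernel frequency step")
    }
  }
  n_frames <- ncol(S)
  n_t <- ncol(kernel$kernel)
  i0 <- which.min(abs(fax - kernel$f0))
  r <- numeric(n_frames)
  for (d in seq_len(nrow(kernel$kernel))) {
    ch <- i0 + (d - kernel$origin_row)
    if (ch < 1 || ch > nrow(S)) next
    k <- kernel$kernel[d, ]
    if (all(k == 0)) next
    x <- c(rep(0, n_t - 1L), S[ch, ])
    y <- stats::filter(x, k, method = "convolution", sides = 1L)
    r <- r + as.numeric(y[n_t:(n_frames + n_t - 1L)])
  }
  r
}

#' @export
print.linear_filter <- function(x, ...) {
  cat(sprintf("<linear_filter> %d taps, step %.3g, %s (origin at %d)\n",
              length(x$coeffs), x$axis_step,
              if (x$causal) "causal" else "acausal", x$origin_index))
  invisible(x)
}
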