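#' Synthetic spectral stimulus ensembles
#'
#' Draws `n_samples` zero-mean Gaussian input spectra over `n_channels`
#' tonotopic channels. Each sample is `intensity_scale * A %*% W %*% z` where
#' `z` is standard Gaussian white noise, `W` is a row-normalized Gaussian
#' smoothing matrix whose width `smoothing_length` (in channel units) sets the
#' correlation range across sound frequency, and `A` is a diagonal intensity
#' profile `exp(-decay_rate * (channel - 1) / n_channels)` so that signal
#' power falls off towards high frequencies, as it does in natural scenes
#' where high-frequency sound propagates poorly.
#'
#' Rows of `W` are normalized to unit L2 norm, so before the `A` profile is
#' applied every channel has unit variance: `intensity_scale` and
#' `decay_rate` are the sole controllers of signal power. The smoothing
#' matrix is truncated (non-circular) at the edges; edge channels genuinely
#' differ, as they do on a real tonotopic axis.
#'
#' @param n_channels number of frequency channels (>= 2).
#' @param n_samples number of independent spectra to draw.
#' @param intensity_scale positive overall scale of the signal.
#' @param decay_rate nonnegative rate of the per-channel intensity decay;
#'   the default `log(10)/2` puts the highest channel at ~10% of the power
#'   of the lowest.
#' @param smoothing_length positive Gaussian smoothing width, channel units.
#' @param seed integer seed; ensembles are bit-reproducible given the seed.
#' @param octave_span frequency extent of the channel axis in octaves.
#' @return a `spectral_ensemble`: list with `samples`
#'   (`n_samples x n_channels`), `freq_axis` (octaves), and all generator
#'   parameters.
#' @examples
#' ens <- make_spectral_ensemble(50, 200, seed = 1)
#' dim(ens$samples)
#' @export
make_spectral_ensemble <- function(n_channels, n_samples,
                                   intensity_scale = 10,
                                   decay_rate = log(10) / 2,
                                   smoothing_length = 5,
                                   seed = 1L,
                                   octave_span = 5) {
  n_channels <- check_count(n_channels, "n_channels", min = 2L)
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  check_positive(intensity_scale, "intensity_scale")
  check_nonnegative(decay_rate, "decay_rate")
  check_positive(smoothing_length, "smoothing_length")
  check_positive(octave_span, "octave_span")

  W <- smoothing_matrix(n_channels, smoothing_length, circular = FALSE)
  A <- intensity_profile(n_channels, decay_rate)
  z <- with_seed(seed, matrix(stats::rnorm(n_channels * n_samples),
                              nrow = n_channels))
  samples <- t(intensity_scale * (A * (W %*% z)))

  structure(
    list(samples = samples,
         freq_axis = seq(0, octave_span, length.out = n_channels),
         intensity_scale = intensity_scale,
         decay_rate = decay_rate,
         smoothing_length = smoothing_length,
         circular = FALSE,
         seed = as.integer(seed)),
    class = "spectral_ensemble"
  )
}

#' Translation-invariant temporal stimulus ensemble
#'
#' As [make_spectral_ensemble()] but with a constant per-channel scale
#' (`decay_rate = 0`) and *circular* Gaussian smoothing, so that the
#' correlation between two time steps depends on their lag only. The
#' resulting analytic correlation matrix is circulant and is exactly
#' diagonalized by the discrete Fourier modes.
#'
#' @param n_steps number of time steps per sample (>= 2).
#' @param n_samples number of samples.
#' @param smoothing_length positive Gaussian smoothing width, step units.
#' @param seed integer seed.
#' @param intensity_scale positive overall signal scale.
#' @param time_step seconds per step (axis bookkeeping only).
#' @return a `spectral_ensemble` whose `freq_axis` slot holds the time axis
#'   in seconds and whose `circular` flag is `TRUE`.
#' @export
make_temporal_ensemble <- function(n_steps, n_samples,
                                   smoothing_length = 5,
                                   seed = 1L,
                                   intensity_scale = 10,
                                   time_step = 1) {
  n_steps <- check_count(n_steps, "n_steps", min = 2L)
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  check_positive(smoothing_length, "smoothing_length")
  check_positive(intensity_scale, "intensity_scale")
  check_positive(time_step, "time_step")

  W <- smoothing_matrix(n_steps, smoothing_length, circular = TRUE)
  z <- with_seed(seed, matrix(stats::rnorm(n_steps * n_samples),
                              nrow = n_steps))
  samples <- t(intensity_scale * (W %*% z))

  structure(
    list(samples = samples,
         freq_axis = (seq_len(n_steps) - 1) * time_step,
         intensity_scale = intensity_scale,
         decay_rate = 0,
         smoothing_length = smoothing_length,
         circular = TRUE,
         seed = as.integer(seed)),
    class = "spectral_ensemble"
  )
}

# Gaussian smoothing matrix, rows L2-normalized. Circular wrapping gives a
# circulant matrix (translation-invariant correlation); truncated otherwise.
smoothing_matrix <- function(n, smoothing_length, circular = FALSE) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  if (circular) d <- pmin(d, n - d)
  W <- exp(-d^2 / (2 * smoothing_length^2))
  W / sqrt(rowSums(W^2))
}

intensity_profile <- function(n, decay_rate) {
  exp(-decay_rate * (seq_len(n) - 1) / n)
}

#' Analytic correlation matrix of a generated ensemble
#'
#' Returns the exact (infinite-sample) input correlation implied by the
#' generator: `R = intensity_scale^2 * A W W' A`, free of sampling noise,
#' together with its eigendecomposition. Because `W` rows have unit L2 norm,
#' `diag(R) = intensity_scale^2 * A^2` independently of the smoothing
#' length, so ensembles with different correlation ranges automatically have
#' equal total signal power.
#'
#' @param ensemble a `spectral_ensemble`, or `NULL` when the parameters are
#'   supplied directly.
#' @param n_channels,intensity_scale,decay_rate,smoothing_length,circular
#'   generator parameters, used when `ensemble` is `NULL`.
#' @return a [correlation_model()].
#' @export
analytic_correlation <- function(ensemble = NULL,
                                 n_channels = NULL,
                                 intensity_scale = 10,
                                 decay_rate = log(10) / 2,
                                 smoothing_length = 5,
                                 circular = FALSE) {
  if (!is.null(ensemble)) {
    stopifnot(inherits(ensemble, "spectral_ensemble"))
    n_channels <- ncol(ensemble$samples)
    intensity_scale <- ensemble$intensity_scale
    decay_rate <- ensemble$decay_rate
    smoothing_length <- ensemble$smoothing_length
    circular <- ensemble$circular
  }
  n_channels <- check_count(n_channels, "n_channels", min = 2L)
  check_positive(intensity_scale, "intensity_scale")
  check_nonnegative(decay_rate, "decay_rate")
  check_positive(smoothing_length, "smoothing_length")

  W <- smoothing_matrix(n_channels, smoothing_length, circular = circular)
  A <- intensity_profile(n_channels, if (circular) 0 else decay_rate)
  R <- intensity_scale^2 * (A * tcrossprod(W)) * rep(A, each = n_channels)
  R <- (R + t(R)) / 2
  correlation_model(R, translation_invariant = circular)
}

#' Two-dimensional modulation power spectrum
#'
#' Signal power of the decorrelated "moving ripple" channels of a
#' translation-invariant spectro-temporal ensemble, over a grid of spectral
#' modulation frequencies `omega_f` (cycles/octave) and temporal modulation
#' frequencies `omega_t` (Hz). The envelope decays exponentially away from
#' the origin, `exp(-corr_f*|omega_f| - corr_t*|omega_t|)`: longer input
#' correlation ranges (`corr_f` in octaves, `corr_t` in seconds) concentrate
#' power at low modulation frequencies. The envelope is normalized so that
#' total power over the grid equals `scale * length(grid)`, i.e. mean channel
#' power `scale`, invariant to the correlation parameters — ensembles that
#' differ only in correlation range carry equal total power.
#'
#' @param omega_f,omega_t modulation-frequency grids, symmetric about 0
#'   (any order; standard DFT order is typical).
#' @param corr_f,corr_t nonnegative correlation-range parameters
#'   (octaves, seconds).
#' @param scale positive SNR scale factor (mean channel power).
#' @return a `modulation_power` object: `power` matrix
#'   (`length(omega_f) x length(omega_t)`), grid axes, parameters.
#' @export
modulation_power_2d <- function(omega_f, omega_t,
                                corr_f = 0.5, corr_t = 0.02,
                                scale = 1) {
  check_positive(scale, "scale")
  check_nonnegative(corr_f, "corr_f")
  check_nonnegative(corr_t, "corr_t")
  check_symmetric_grid(omega_f, "omega_f")
  check_symmetric_grid(omega_t, "omega_t")

  env <- exp(-(corr_f * abs(omega_f))) %o% exp(-(corr_t * abs(omega_t)))
  power <- scale * env * (length(env) / sum(env))

  structure(
    list(power = power, omega_f = omega_f, omega_t = omega_t,
         corr_f = corr_f, corr_t = corr_t, scale = scale),
    class = "modulation_power"
  )
}

check_symmetric_grid <- function(omega, name) {
  if (length(omega) < 2L || !is.numeric(omega)) {
    stop_param(sprintf("`%s` must be a numeric grid", name))
  }
  pos <- sort(omega[omega > 0])
  neg <- sort(-omega[omega < 0])
  if (length(pos) - length(neg) > 1L || length(neg) > length(pos) ||
      (length(neg) > 0 &&
       max(abs(pos[seq_along(neg)] - neg)) > 1e-8 * max(abs(omega)))) {
    stop_param(sprintf("`%s` must be symmetric about the origin", name))
  }
  invisible(omega)
}

#' Log-frequency spectrogram of an audio waveform
#'
#' Windowed Fourier power of a mono waveform, resampled onto a log2-spaced
#' (octave) frequency axis as a crude model of cochlear frequency analysis,
#' optionally log-compressed, and mean-subtracted per channel. The
#' per-channel baseline is returned separately so the raw power can be
#' reconstructed.
#'
#' @param waveform numeric vector of audio samples, or the result of
#'   [read_wav()].
#' @param sample_rate samples per second (ignored if `waveform` is a
#'   `wav_audio` object).
#' @param window_len,hop analysis window length and hop, seconds.
#' @param n_channels number of log-spaced frequency channels.
#' @param log_compress apply `log(power + eps)` compression before mean
#'   subtraction.
#' @param f_min lowest channel center (Hz); defaults to two DFT bins.
#' @param eps additive floor used by the log compression.
#' @return a `spectrogram`: `power` (`n_channels x n_frames`, zero-mean per
#'   channel), `mean_power`, `freq_axis` (octaves re 1 Hz), `time_axis`
#'   (s), `window` descriptor and the `log_compressed` flag.
#' @export
spectrogram_from_waveform <- function(waveform, sample_rate = NULL,
                                      window_len = 0.02, hop = 0.01,
                                      n_channels = 32,
                                      log_compress = FALSE,
                                      f_min = NULL, eps = 1e-10) {
  if (inherits(waveform, "wav_audio")) {
    sample_rate <- waveform$sample_rate
    waveform <- waveform$samples
  }
  if (length(waveform) == 0) stop_param("waveform is empty")
  check_positive(sample_rate, "sample_rate")
  check_positive(window_len, "window_len")
  check_positive(hop, "hop")
  n_channels <- check_count(n_channels, "n_channels", min = 2L)

  wl <- max(4L, round(window_len * sample_rate))
  if (wl > length(waveform)) {
    stop_param("window_len is longer than the waveform")
  }
  hopn <- max(1L, round(hop * sample_rate))

  sg <- signal::specgram(waveform, n = wl, Fs = sample_rate,
                         window = signal::hanning(wl),
                         overlap = wl - hopn)
  pow_lin <- Mod(sg$S)^2          # bins x frames
  f_lin <- sg$f
  keep <- f_lin > 0
  pow_lin <- pow_lin[keep, , drop = FALSE]
  f_lin <- f_lin[keep]

  if (is.null(f_min)) f_min <- 2 * sample_rate / wl
  f_min <- max(f_min, min(f_lin))
  centers <- 2^seq(log2(f_min), log2(max(f_lin)), length.out = n_channels)

  # assign each linear bin to the nearest channel center on the log2 axis
  assignment <- vapply(log2(f_lin), function(lf) {
    which.min(abs(log2(centers) - lf))
  }, integer(1))
  power <- matrix(0, n_channels, ncol(pow_lin))
  for (ch in seq_len(n_channels)) {
    rows <- which(assignment == ch)
    if (length(rows) == 0) {
      rows <- which.min(abs(log2(f_lin) - log2(centers[ch])))
    }
    power[ch, ] <- colMeans(pow_lin[rows, , drop = FALSE])
  }

  if (log_compress) power <- log(power + eps)
  mean_power <- rowMeans(power)
  power <- power - mean_power

  structure(
    list(power = power,
         mean_power = mean_power,
         freq_axis = log2(centers),
         time_axis = as.numeric(sg$t),
         window = list(type = "hanning", length = window_len, hop = hop),
         log_compressed = log_compress),
    class = "spectrogram"
  )
}

#' @export
print.spectral_ensemble <- function(x, ...) {
  cat(sprintf(
    "<spectral_ensemble> %d samples x %d channels (%s smoothing %.3g, scale %.3g, decay %.3g, seed %d)\n",
    nrow(x$samples), ncol(x$samples),
    if (x$circular) "circular" else "truncated",
    x$smoothing_length, x$intensity_scale, x$decay_rate, x$seed))
  invisible(x)
}

#' @export
print.modulation_power <- function(x, ...) {
  cat(sprintf(
    "<modulation_power> %d x %d grid, corr_f %.3g oct, corr_t %.3g s, scale %.3g\n",
    nrow(x$power), ncol(x$power), x$corr_f, x$corr_t, x$scale))
  invisible(x)
}
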