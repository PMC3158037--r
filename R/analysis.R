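#' Modulation transfer function of a filter kernel
#'
#' Magnitude of the DFT of a 1-D filter or 2-D STRF kernel over its
#' modulation-frequency grid (cycles per octave for the spectral axis, Hz
#' for the temporal axis). Circular shifts of the kernel (e.g. the centred
#' frequency-offset axis of an STRF) leave the magnitude unchanged.
#'
#' @param kernel a [linear_filter()], [strf_kernel()], or bare numeric
#'   vector/matrix.
#' @param normalization optional positive value the MTF peak is scaled to
#'   (per-neuron peak normalization); `NULL` leaves the raw magnitude.
#' @return an `mtf`: `magnitude` (same shape as the kernel's DFT, standard
#'   DFT order), grid axes `omega_f`/`omega_t` (2-D) or `omega` (1-D), and
#'   the normalization descriptor.
#' @export
mtf_of <- function(kernel, normalization = NULL) {
  if (inherits(kernel, "linear_filter")) {
    x <- kernel$coeffs
    step <- kernel$axis_step
  } else if (inherits(kernel, "strf_kernel")) {
    x <- kernel$kernel
    step <- c(kernel$freq_step, kernel$time_step)
  } else if (is.matrix(kernel)) {
    x <- kernel
    step <- c(1, 1)
  } else {
    x <- as.numeric(kernel)
    step <- 1
  }
  if (length(x) == 0 || all(x == 0)) stop_param("kernel is empty or all zero")

  if (is.matrix(x)) {
    mag <- Mod(apply_fft2(x))
    axes <- list(omega_f = dft_frequencies(nrow(x), step[1]),
                 omega_t = dft_frequencies(ncol(x), step[2]))
  } else {
    mag <- Mod(stats::fft(x))
    axes <- list(omega = dft_frequencies(length(x), step[1]))
  }
  norm_desc <- "none"
  if (!is.null(normalization)) {
    check_positive(normalization, "normalization")
    mag <- mag * (normalization / max(mag))
    norm_desc <- sprintf("peak = %g", normalization)
  }
  structure(c(list(magnitude = mag, normalization = norm_desc), axes),
            class = "mtf")
}

#' Peak and cutoff modulation frequencies of an MTF
#'
#' For a 1-D MTF the peak is the argmax of the magnitude over nonnegative
#' frequencies, with ties resolved toward the lowest frequency
#' (conservative with respect to band-pass claims). For a 2-D MTF the
#' per-axis peak (best modulation frequency) is the argmax along the axis
#' slice through the origin, i.e. with the other modulation frequency held
#' at zero: the joint argmax of a 2-D gain surface is degenerate along the
#' level curve of the underlying signal power where the gain is maximal,
#' whereas each axis slice is a proper 1-D gain profile with a unique
#' best frequency. The cutoff per axis is the largest
#' nonnegative frequency at which the magnitude (maximized over the other
#' axis, in 2-D) still reaches `rel_threshold` times the quadrant maximum —
#' assembled kernels never reach exactly zero, so an exact-zero cutoff is
#' not meaningful for measured MTFs.
#'
#' @param mtf an [mtf_of()] result, or a bare nonnegative vector
#'   (interpreted as magnitude over DFT-ordered frequencies).
#' @param rel_threshold cutoff threshold as a fraction of the peak,
#'   in (0, 1).
#' @return a `filter_metrics` list: `peak_mod_freq`, `peak_index`,
#'   `cutoff_freq` (per axis), `shape_class`.
#' @export
peak_and_cutoff <- function(mtf, rel_threshold = 0.05) {
  if (!(rel_threshold > 0 && rel_threshold < 1)) {
    stop_param("`rel_threshold` must lie strictly between 0 and 1")
  }
  if (!inherits(mtf, "mtf")) mtf <- as_mtf_vector(mtf)
  mag <- mtf$magnitude
  if (all(mag == 0)) stop_param("MTF is identically zero")

  if (is.matrix(mag)) {
    fpos <- order(mtf$omega_f)[mtf$omega_f[order(mtf$omega_f)] >= 0]
    tpos <- order(mtf$omega_t)[mtf$omega_t[order(mtf$omega_t)] >= 0]
    quad <- mag[fpos, tpos, drop = FALSE]
    of <- mtf$omega_f[fpos]
    ot <- mtf$omega_t[tpos]
    pk <- c(which.max(quad[, 1]), which.max(quad[1, ]))  # axis slices;
                                                 # first tie -> lowest freq
    thr <- rel_threshold * max(quad)
    prof_f <- apply(quad, 1, max)
    prof_t <- apply(quad, 2, max)
    metrics <- list(
      peak_mod_freq = c(spectral = of[pk[1]], temporal = ot[pk[2]]),
      peak_index = pk,
      cutoff_freq = c(spectral = max(of[prof_f >= thr]),
                      temporal = max(ot[prof_t >= thr])),
      shape_class = if (pk[1] > 1 || pk[2] > 1) "band-pass" else "low-pass")
  } else {
    pos <- which(mtf$omega >= 0)
    om <- mtf$omega[pos]
    prof <- mag[pos][order(om)]
    om <- sort(om)
    peak <- which.max(prof)                     # which.max takes first tie
    thr <- rel_threshold * max(prof)
    metrics <- list(
      peak_mod_freq = om[peak],
      peak_index = peak,
      cutoff_freq = max(om[prof >= thr]),
      shape_class = if (peak > 1) "band-pass" else "low-pass")
  }
  structure(metrics, class = "filter_metrics")
}

as_mtf_vector <- function(x) {
  x <- as.numeric(x)
  structure(list(magnitude = x, omega = dft_frequencies(length(x)),
                 normalization = "none"),
            class = "mtf")
}

#' Band-pass versus low-pass classification of a 1-D profile
#'
#' A nonnegative magnitude profile over ascending nonnegative frequencies
#' (e.g. a gain profile over channel index, or an MTF quadrant profile) is
#' band-pass when its maximum over nonzero frequencies exceeds the
#' zero-frequency (first-bin) magnitude by more than `margin` (relative);
#' otherwise low-pass.
#'
#' @param profile nonnegative numeric vector, lowest frequency first.
#' @param margin relative excess required to call the profile band-pass.
#' @return `"band-pass"` or `"low-pass"`.
#' @export
classify_shape <- function(profile, margin = 0.1) {
  profile <- as.numeric(profile)
  if (any(profile < 0)) stop_param("profile must be nonnegative")
  if (length(profile) < 2L) return("low-pass")
  if (max(profile[-1]) > (1 + margin) * profile[1]) "band-pass" else "low-pass"
}

#' Excitatory/inhibitory lobe metrics of a kernel
#'
#' Lobes are maximal contiguous runs of same-sign coefficients whose peak
#' magnitude reaches `noise_floor` times the global maximum and whose
#' length reaches `min_run` taps. Reported: lobe counts by sign, the width
#' (at half the lobe peak) of the main lobe — the lobe containing the
#' global absolute maximum — in axis units, and the inhibitory strength
#' ratio `sum(|negative lobes|) / sum(|positive lobes|)`.
#'
#' @param kernel a [linear_filter()] or numeric vector (e.g. one row of an
#'   STRF kernel).
#' @param axis_step tap spacing, used when `kernel` is a bare vector.
#' @param noise_floor fraction of the global max below which a lobe is
#'   ignored.
#' @param min_run minimum lobe length in taps.
#' @return a `filter_metrics` list: `n_excitatory_lobes`,
#'   `n_inhibitory_lobes`, `main_lobe_width`, `inhibitory_strength_ratio`.
#' @export
lobe_metrics <- function(kernel, axis_step = NULL, noise_floor = 0.05,
                         min_run = 2L) {
  if (inherits(kernel, "linear_filter")) {
    x <- kernel$coeffs
    if (is.null(axis_step)) axis_step <- kernel$axis_step
  } else {
    x <- as.numeric(kernel)
    if (is.null(axis_step)) axis_step <- 1
  }
  if (all(x == 0)) {
    return(structure(list(n_excitatory_lobes = 0L, n_inhibitory_lobes = 0L,
                          main_lobe_width = 0, inhibitory_strength_ratio = 0),
                     class = "filter_metrics"))
  }
  mx <- max(abs(x))
  s <- sign(x)
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  n_exc <- 0L
  n_inh <- 0L
  sum_pos <- 0
  sum_neg <- 0
  main_width <- 0
  imax <- which.max(abs(x))
  for (j in seq_along(runs$lengths)) {
    if (runs$values[j] == 0) next
    seg <- x[starts[j]:ends[j]]
    if (max(abs(seg)) < noise_floor * mx || length(seg) < min_run) next
    if (runs$values[j] > 0) {
      n_exc <- n_exc + 1L
      sum_pos <- sum_pos + sum(abs(seg))
    } else {
      n_inh <- n_inh + 1L
      sum_neg <- sum_neg + sum(abs(seg))
    }
    if (imax >= starts[j] && imax <= ends[j]) {
      main_width <- sum(abs(seg) >= max(abs(seg)) / 2) * axis_step
    }
  }
  structure(
    list(n_excitatory_lobes = n_exc,
         n_inhibitory_lobes = n_inh,
         main_lobe_width = main_width,
         inhibitory_strength_ratio =
           if (sum_pos > 0) sum_neg / sum_pos else Inf),
    class = "filter_metrics"
  )
}

#' Whitening-limit flatness diagnostic
#'
#' In the high-SNR limit the optimal gain satisfies `g ~ S^(-1/2)`, so
#' `g^2 * S` is constant over the passband (output power equalized across
#' channels). This reports the maximum relative deviation of `g^2 * S`
#' from its mean over the channels with `S / N >= snr_threshold` and
#' `g > 0`.
#'
#' @param gains,powers matching nonnegative vectors.
#' @param noise a [noise_spec()].
#' @param snr_threshold S/N above which a channel counts as high-SNR.
#' @return list with `applicable` flag, `deviation` (max relative, `NA`
#'   when no channel qualifies), and `n_channels` used.
#' @export
whitening_flatness <- function(gains, powers, noise, snr_threshold = 100) {
  noise <- as_noise_spec(noise)
  if (length(gains) != length(powers)) {
    stop_param("`gains` and `powers` must have the same length")
  }
  idx <- powers / noise$input_noise_var >= snr_threshold & gains > 0
  if (!any(idx)) {
    return(list(applicable = FALSE, deviation = NA_real_, n_channels = 0L))
  }
  w <- gains[idx]^2 * powers[idx]
  list(applicable = TRUE,
       deviation = max(abs(w / mean(w) - 1)),
       n_channels = sum(idx))
}

#' Population-average MTF
#'
#' Averages MTF magnitudes across kernels after normalizing each to a
#' common peak value, the way per-neuron MTFs are pooled into a population
#' pattern.
#'
#' @param mtfs list of [mtf_of()] results with identical grids.
#' @param peak_value common peak each MTF is normalized to before
#'   averaging.
#' @return an `mtf` with the averaged magnitude.
#' @export
average_mtf <- function(mtfs, peak_value = 1) {
  stopifnot(length(mtfs) >= 1L, all(vapply(mtfs, inherits, TRUE, "mtf")))
  check_positive(peak_value, "peak_value")
  mags <- lapply(mtfs, function(m) m$magnitude * (peak_value / max(m$magnitude)))
  out <- mtfs[[1]]
  out$magnitude <- Reduce(`+`, mags) / length(mags)
  out$normalization <- sprintf("per-kernel peak = %g, averaged", peak_value)
  out
}

#' @export
print.filter_metrics <- function(x, ...) {
  cat("<filter_metrics>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]], digits = 4),
                                        collapse = ", ")))
  }
  invisible(x)
}
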