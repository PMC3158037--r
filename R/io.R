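# Minimal 16-bit PCM mono WAV I/O and plain-text persistence for kernels,
# ensembles and metrics. Arrays go to TSV, parameters to a JSON sidecar, so
# every artifact is diffable and regenerable from its embedded config.

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file path.
#' @return a `wav_audio` list: `samples` (numeric in \[-1, 1\]) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_param("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_param("not a WAVE file: ", path)

  sample_rate <- NULL
  n_channels <- NULL
  bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
      if (fmt[1] != 1 || bits != 16) {
        stop_param("only 16-bit PCM WAV is supported")
      }
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, size = 2,
                         signed = TRUE, endian = "little")
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(samples) && !is.null(sample_rate)) break
  }
  if (is.null(samples) || is.null(sample_rate)) {
    stop_param("malformed WAV file: ", path)
  }
  if (n_channels > 1) {
    samples <- colMeans(matrix(samples, nrow = n_channels))
  }
  structure(list(samples = samples / 32767, sample_rate = sample_rate),
            class = "wav_audio")
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in \[-1, 1\] (clipped otherwise).
#' @param sample_rate Hz.
#' @param path output path.
#' @export
write_wav <- function(samples, sample_rate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")      # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")     # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Persist a filter kernel as TSV + JSON sidecar
#'
#' 1-D filters and 2-D STRF kernels are written as tab-separated numeric
#' tables; axes, flags and generation parameters go to `<path>.json`.
#'
#' @param kernel a [linear_filter()] or [strf_kernel()].
#' @param path output TSV path.
#' @param config optional generation parameters echoed into the sidecar.
#' @export
save_kernel <- function(kernel, path, config = NULL) {
  if (inherits(kernel, "linear_filter")) {
    utils::write.table(data.frame(coeff = kernel$coeffs), path,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    meta <- list(type = "linear_filter", axis_step = kernel$axis_step,
                 causal = kernel$causal, origin_index = kernel$origin_index)
  } else if (inherits(kernel, "strf_kernel")) {
    utils::write.table(kernel$kernel, path, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    meta <- list(type = "strf_kernel", freq_step = kernel$freq_step,
                 time_step = kernel$time_step, f0 = kernel$f0,
                 causal = kernel$causal, origin_row = kernel$origin_row)
  } else {
    stop_param("unsupported kernel type")
  }
  if (!is.null(config)) meta$config <- config
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a kernel written by [save_kernel()]
#' @param path TSV path (with `<path>.json` sidecar alongside).
#' @return a [linear_filter()] or [strf_kernel()].
#' @export
load_kernel <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(meta$type, "linear_filter")) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    linear_filter(tab$coeff, axis_step = meta$axis_step,
                  causal = meta$causal, origin_index = meta$origin_index)
  } else if (identical(meta$type, "strf_kernel")) {
    m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
    dimnames(m) <- NULL
    strf_kernel(m, freq_step = meta$freq_step, time_step = meta$time_step,
                f0 = meta$f0, causal = meta$causal,
                origin_row = meta$origin_row)
  } else {
    stop_param("unknown kernel type in sidecar: ", meta$type)
  }
}
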