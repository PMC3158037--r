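# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_param <- function(...) {
  stop(..., call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_param(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_param(sprintf("`%s` must be a single nonnegative finite number", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    stop_param(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Index vector that moves the zero-lag/zero-frequency element of a length-n
# DFT-ordered vector to the centre (classic fftshift).
fftshift_index <- function(n) {
  h <- floor(n / 2)
  c((h + 1L):n, seq_len(h))
}

# DFT frequencies in cycles per unit for n samples at spacing `step`,
# in standard DFT order (0, 1, ..., floor(n/2), -(ceiling(n/2)-1), ..., -1).
dft_frequencies <- function(n, step = 1) {
  k <- c(0:floor(n / 2), seq.int(-(ceiling(n / 2) - 1L), -1L))
  if (n %% 2 == 0) k <- c(0:(n / 2), seq.int(-(n / 2 - 1L), -1L))
  k[seq_len(n)] / (n * step)
}
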