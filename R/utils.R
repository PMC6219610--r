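# Internal helpers shared across modules.

abort_param <- function(msg) rlang::abort(msg, class = "ufd_parameter_error")

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_param(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

#' @noRd
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# Analytic signal of a real vector (one-sided spectrum, FFT based).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Frequency axis of an n-point spectrum reordered to span (-fs/2, fs/2],
# i.e. bins k*fs/n for k in (-n/2, n/2]. Returns the reordering index and
# the frequencies so that spectrum[order] is monotonically increasing in f.
spectrum_axis <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n   # leaves +n/2 positive for even n
  ord <- order(k)
  list(freq = k[ord] * fs / n, order = ord)
}

# Deterministic stream of child seeds below 2^31, drawn once from `seed`.
# Restores the caller's RNG state so seeded code stays reproducible around it.
derive_seeds <- function(seed, n) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Sum complex matrix rows by group (rowsum() does not accept complex input).
rowsum_complex <- function(x, group, ngroups) {
  g <- factor(group, levels = seq_len(ngroups))
  re <- rowsum(Re(x), g)
  im <- rowsum(Im(x), g)
  idx <- as.integer(rownames(re))
  out <- matrix(0 + 0i, ngroups, ncol(x))
  out[idx, ] <- re + 1i * im
  out
}
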