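#' Spectrogram specification
#'
#' Parameters of the per-pixel short-time Fourier analysis used for blood
#' velocity estimation. The default Hann window of 64 frames (32 ms at the
#' 2 kHz compounded rate) with 75% overlap resolves the few-Hz cardiac
#' modulation of the velocity envelope while keeping useful spectral
#' resolution.
#'
#' @param window_length Window length in frames.
#' @param overlap Overlap between consecutive windows in frames.
#' @param window Window shape, `"hann"` or `"rect"`.
#' @param zero_pad Zero-padding factor (FFT length = factor x window).
#' @return An object of class `spectrogram_spec`.
#' @export
spectrogram_spec <- function(window_length = 64, overlap = 48,
                             window = c("hann", "rect"), zero_pad = 1) {
  window <- match.arg(window)
  if (overlap < 0 || overlap >= window_length) {
    abort_param("Require 0 <= overlap < window_length.")
  }
  if (zero_pad < 1 || zero_pad != round(zero_pad)) {
    abort_param("`zero_pad` must be a positive integer factor.")
  }
  structure(list(window_length = as.integer(window_length),
                 overlap = as.integer(overlap), window = window,
                 zero_pad = as.integer(zero_pad)),
            class = "spectrogram_spec")
}

spec_window <- function(spec) {
  switch(spec$window, hann = hann_window(spec$window_length),
         rect = rep(1, spec$window_length))
}

# Batched short-time power spectra: x is a (series x pixels) matrix of
# complex samples (columns are independent pixel series). Returns, per
# slice, an (nfft x npix) power matrix normalized so that summing over
# frequency reproduces the windowed slice energy (discrete Parseval).
stft_power <- function(x, spec, fs) {
  n <- nrow(x)
  L <- spec$window_length
  if (n < L) abort_param("Series shorter than the spectrogram window.")
  w <- spec_window(spec)
  nfft <- L * spec$zero_pad
  hop <- L - spec$overlap
  starts <- seq(1, n - L + 1, by = hop)
  ax <- spectrum_axis(nfft, fs)
  power <- lapply(starts, function(s) {
    seg <- x[s:(s + L - 1), , drop = FALSE] * w
    if (nfft > L) seg <- rbind(seg, matrix(0i, nfft - L, ncol(seg)))
    P <- Mod(stats::mvfft(seg))^2 / nfft
    P[ax$order, , drop = FALSE]
  })
  list(times = (starts - 1 + (L - 1) / 2) / fs, freq = ax$freq,
       power = power)
}

#' Per-pixel Doppler spectrogram
#'
#' Short-time power spectra of one pixel's complex (IQ) time series. The
#' frequency axis spans `(-fs/2, fs/2]`; each time slice satisfies the
#' discrete Parseval identity (summed spectral power equals the windowed
#' signal energy).
#'
#' @param signal Complex vector, one pixel's frame series.
#' @param spec A [spectrogram_spec()].
#' @param fs Frame rate in Hz.
#' @return A list of class `ufd_spectrogram` with `times` (s, slice
#'   centers), `freq` (Hz) and `power` (frequency x slice matrix).
#' @export
pixel_spectrogram <- function(signal, spec = spectrogram_spec(), fs) {
  stopifnot(inherits(spec, "spectrogram_spec"))
  check_positive(fs, "fs")
  out <- stft_power(matrix(as.complex(signal), ncol = 1), spec, fs)
  structure(list(times = out$times, freq = out$freq,
                 power = do.call(cbind, lapply(out$power, as.vector))),
            class = "ufd_spectrogram")
}

#' Mean blood speed from one spectral slice
#'
#' First statistical moment of the Doppler power spectrum, taken on the
#' speed magnitude: `v = (sum P(f) |f| / sum P(f)) * c / (2 f0)` over the
#' bins whose power exceeds `noise_floor`. Flow direction is deliberately
#' collapsed (the resistivity index is direction-free). Slices with no
#' power above the floor are invalid and return `NA` rather than zero.
#'
#' @param power Numeric vector of spectral power for one time slice.
#' @param freq Frequency axis in Hz (same length).
#' @param f0 Transducer center frequency in Hz.
#' @param sound_speed Speed of sound in m/s.
#' @param noise_floor Per-bin power level at or below which bins are
#'   excluded.
#' @return Mean axial speed in m/s, or `NA` if the slice is below the
#'   noise floor.
#' @examples
#' f <- seq(-1000, 1000, by = 10)
#' p <- as.numeric(f == 1000)
#' mean_velocity(p, f, 6.4e6, 1540)  # 0.1203 m/s
#' @export
mean_velocity <- function(power, freq, f0, sound_speed = 1540,
                          noise_floor = 0) {
  stopifnot(length(power) == length(freq))
  check_positive(f0, "f0")
  band <- which(power > noise_floor)
  tot <- sum(power[band])
  if (length(band) == 0 || !is.finite(tot) || tot <= 0) return(NA_real_)
  f_mean <- sum(power[band] * abs(freq[band])) / tot
  f_mean * sound_speed / (2 * f0)
}

#' Resistivity index of a velocity trace
#'
#' `RI = (v_max - v_min) / v_max` over the covered cardiac cycle(s):
#' the ratio between the range of blood flow speed and the maximum blood
#' flow speed. Constant flow gives 0, diastolic flow reaching zero gives 1.
#' The index is invariant to a uniform rescaling of the trace.
#'
#' @param speed Numeric vector of mean axial speeds (m/s); `NA` entries
#'   (below-noise slices) are dropped.
#' @param min_speed Validity floor: if the maximum speed does not exceed
#'   it, the trace is considered noise and `NA` is returned.
#' @return Resistivity index in \[0, 1\], or `NA` if invalid.
#' @examples
#' resistivity_index(c(0.10, 0.07, 0.04, 0.06))  # 0.6
#' @export
resistivity_index <- function(speed, min_speed = 0) {
  speed <- speed[!is.na(speed)]
  if (length(speed) < 2) return(NA_real_)
  v_max <- max(speed)
  if (v_max <= min_speed || v_max <= 0) return(NA_real_)
  (v_max - min(speed)) / v_max
}

#' Resistivity map of a filtered block
#'
#' Per-pixel time-frequency analysis of a clutter-filtered block: each
#' unmasked pixel's IQ series is turned into a spectrogram, the mean blood
#' speed of every time slice is estimated as the first spectral moment, and
#' the resistivity index of the resulting velocity trace is computed. The
#' block must span at least one cardiac cycle (a 0.5 s block covers two at
#' the rabbit heart rate of about 4 Hz). Per-pixel noise floors are set at
#' `noise_floor_factor` times the median spectral bin power of the pixel,
#' so only spectral bins carrying blood signal enter the moment.
#'
#' @param x An `iq_block` or `svd_filtered_block`.
#' @param spec A [spectrogram_spec()].
#' @param heart_rate Cardiac frequency in Hz (sets the minimum duration and
#'   the cycle-coverage requirement).
#' @param mask Optional logical matrix of pixels to evaluate (e.g. a power
#'   mask of vessel pixels); `NULL` evaluates everywhere.
#' @param noise_floor_factor Multiple of the per-pixel median bin power
#'   used as noise floor.
#' @param min_speed Speed validity floor passed to [resistivity_index()].
#' @return A `parametric_map` of kind `"resistivity"`; masked or invalid
#'   pixels are `NA`.
#' @export
resistivity_map <- function(x, spec = spectrogram_spec(), heart_rate = 4,
                            mask = NULL, noise_floor_factor = 2,
                            min_speed = 0) {
  if (inherits(x, "svd_filtered_block")) x <- x$block
  stopifnot(inherits(x, "iq_block"))
  d <- dim(x$data)
  duration <- d[3] / x$fs
  if (duration < 1 / heart_rate) {
    abort_param(sprintf(
      "Block spans %.3g s but one cardiac cycle needs %.3g s.",
      duration, 1 / heart_rate))
  }
  npix <- d[1] * d[2]
  use <- if (is.null(mask)) rep(TRUE, npix) else as.vector(mask)
  X <- t(matrix(x$data, npix, d[3])[use, , drop = FALSE])  # time x pixels

  st <- stft_power(X, spec, x$fs)
  n_slice <- length(st$power)
  n_use <- ncol(X)
  # per-pixel noise floor: factor x median bin power across all slices
  med <- apply(do.call(rbind, st$power), 2, stats::median)
  V <- matrix(NA_real_, n_slice, n_use)
  absf <- abs(st$freq)
  scale <- x$sound_speed / (2 * x$center_frequency)
  for (s in seq_len(n_slice)) {
    P <- st$power[[s]]
    P[P <= noise_floor_factor * rep(med, each = nrow(P))] <- 0
    tot <- colSums(P)
    v <- (colSums(P * absf) / tot) * scale
    v[!is.finite(v) | tot <= 0] <- NA_real_
    V[s, ] <- v
  }

  ri <- rep(NA_real_, n_use)
  cycle_s <- 1 / heart_rate
  for (j in seq_len(n_use)) {
    ok <- !is.na(V[, j])
    # slice centers plus the window half-widths must cover one full cycle
    if (sum(ok) >= 2 && diff(range(st$times[ok])) >= cycle_s -
        spec$window_length / x$fs) {
      ri[j] <- resistivity_index(V[, j], min_speed = min_speed)
    }
  }
  out <- rep(NA_real_, npix)
  out[use] <- pmin(pmax(ri, 0), 1)
  parametric_map(matrix(out, d[1], d[2]), "resistivity",
                 time_min = x$t0 / 60)
}
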