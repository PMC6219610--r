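#' Linear-array geometry
#'
#' Element layout and channel-data sampling of a linear ultrasound array.
#' The probe used in this kind of study is a 6.4 MHz linear array; element
#' count and pitch are configurable (defaults: 128 elements, 0.3 mm pitch,
#' centered on x = 0).
#'
#' @param n_elements Number of elements.
#' @param pitch Element pitch in m.
#' @param fs Channel-data sampling frequency in Hz; must give at least 4
#'   samples per period of the transmit frequency for accurate delay
#'   interpolation.
#' @return An object of class `array_geometry` with element x positions.
#' @export
array_geometry <- function(n_elements = 128, pitch = 3e-4, fs = 32e6) {
  check_positive(pitch, "pitch")
  check_positive(fs, "fs")
  if (n_elements < 2) abort_param("Need at least 2 elements.")
  x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(list(n_elements = as.integer(n_elements), pitch = pitch,
                 positions = x, fs = fs),
            class = "array_geometry")
}

plane_wave_delay <- function(z, x, xe, angle_deg, c0) {
  th <- angle_deg * pi / 180
  # transmit: plane wave referenced to the array center; receive: exact
  # point-to-element path
  (z * cos(th) + x * sin(th) + sqrt(z^2 + (x - xe)^2)) / c0
}

#' Simulate plane-wave channel data from point scatterers
#'
#' Raw RF traces received by every array element after a tilted plane-wave
#' transmission into a medium of point scatterers. Each scatterer produces
#' a 3-cycle Hann-tapered tone burst at the two-way delay (plane-wave
#' transmit path referenced to the array center plus exact return path to
#' the element). Scatterers outside the lateral aperture or at nonpositive
#' depth are excluded with a warning. An empty scatterer list yields a
#' noise-only record.
#'
#' @param scatterers Data frame with columns `x`, `z` (m) and optionally
#'   `amplitude` (default 1).
#' @param geometry An [array_geometry()].
#' @param config An [acquisition_config()] (supplies the transmit frequency
#'   and sound speed).
#' @param angle Plane-wave tilt angle in degrees.
#' @param n_cycles Cycles in the transmit burst.
#' @param max_depth Imaging depth in m defining the record length; default
#'   covers the deepest scatterer.
#' @param noise_sd Standard deviation of additive white noise.
#' @param seed Seed for the noise.
#' @return A list of class `channel_data`: `data` (samples x elements),
#'   `fs`, `angle`, `geometry`, `t0 = 0`.
#' @export
simulate_rf_plane_wave <- function(scatterers, geometry, config, angle = 0,
                                   n_cycles = 3, max_depth = NULL,
                                   noise_sd = 0, seed = 1) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(config, "acq_config"))
  f0 <- config$center_frequency
  c0 <- config$sound_speed
  if (geometry$fs < 4 * f0) {
    abort_param("Channel sampling below 4 samples per transmit period.")
  }
  sc <- tibble::as_tibble(scatterers)
  if (nrow(sc) > 0) {
    if (!all(c("x", "z") %in% names(sc))) {
      abort_param("`scatterers` needs columns `x` and `z`.")
    }
    if (!"amplitude" %in% names(sc)) sc$amplitude <- 1
    half_ap <- max(abs(geometry$positions)) + geometry$pitch
    inside <- sc$z > 0 & abs(sc$x) <= half_ap
    if (any(!inside)) {
      warning(sprintf("%d scatterer(s) outside the field of view excluded.",
                      sum(!inside)), call. = FALSE)
      sc <- sc[inside, ]
    }
  }
  burst_s <- n_cycles / f0
  if (is.null(max_depth)) {
    max_depth <- if (nrow(sc) > 0) max(sc$z) * 1.2 else 0.02
  }
  t_max <- 2.2 * max_depth / c0 + burst_s
  n_samp <- ceiling(t_max * geometry$fs)
  t <- (seq_len(n_samp) - 1) / geometry$fs

  pulse <- function(tt) {
    inside <- tt >= 0 & tt <= burst_s
    out <- numeric(length(tt))
    out[inside] <- sin(2 * pi * f0 * tt[inside]) *
      0.5 * (1 - cos(2 * pi * tt[inside] / burst_s))
    out
  }

  data <- matrix(0, n_samp, geometry$n_elements)
  if (nrow(sc) > 0) {
    for (e in seq_len(geometry$n_elements)) {
      tau <- plane_wave_delay(sc$z, sc$x, geometry$positions[e], angle, c0)
      for (k in seq_len(nrow(sc))) {
        data[, e] <- data[, e] + sc$amplitude[k] * pulse(t - tau[k])
      }
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    data <- data + matrix(stats::rnorm(length(data), 0, noise_sd),
                          nrow(data))
  }
  structure(list(data = data, fs = geometry$fs, angle = angle,
                 geometry = geometry, t0 = 0,
                 center_frequency = f0, sound_speed = c0,
                 burst_s = burst_s),
            class = "channel_data")
}

#' Delay-and-sum beamforming of plane-wave channel data
#'
#' Reconstructs a complex image on a pixel grid from one tilted plane-wave
#' transmission: for every pixel the analytic channel signals are sampled
#' (linear interpolation) at the two-way delay `(z cos(theta) + x
#' sin(theta) + sqrt(z^2 + (x - xe)^2)) / c` and summed across elements
#' with the chosen apodization. The receive aperture is F-number limited:
#' an element contributes to a pixel only if its lateral offset is within
#' `z / (2 * f_number)`, the standard dynamic-aperture rule that keeps
#' steep-angle echoes from corrupting shallow pixels. Delays beyond the
#' record contribute zero.
#' The image phase is rotated to baseband so scatterers appear as smooth
#' complex maxima. Beamforming is linear in the channel data.
#'
#' @param channels A `channel_data` record from [simulate_rf_plane_wave()].
#' @param grid_z,grid_x Pixel coordinates in m (depth positive downward,
#'   pixel \[1, 1\] shallow-left).
#' @param apodization `"rect"` (default) or `"hann"` receive apodization.
#' @param f_number Receive F-number of the dynamic aperture (aperture
#'   half-width `z / (2 * f_number)`); `0` disables the limit.
#' @param angle Transmit angle override in degrees; defaults to the
#'   record's own angle.
#' @return An object of class `angled_image`: complex matrix
#'   `length(grid_z) x length(grid_x)` plus grid metadata and the angle.
#' @export
das_beamform <- function(channels, grid_z, grid_x,
                         apodization = c("rect", "hann"),
                         f_number = 1,
                         angle = channels$angle) {
  stopifnot(inherits(channels, "channel_data"))
  apodization <- match.arg(apodization)
  geom <- channels$geometry
  c0 <- channels$sound_speed
  n_samp <- nrow(channels$data)
  nz <- length(grid_z); nx <- length(grid_x)

  apod <- switch(apodization,
                 rect = rep(1, geom$n_elements),
                 hann = hann_window(geom$n_elements))
  # analytic (one-sided spectrum) channel signals for complex output
  A <- apply(channels$data, 2, analytic_signal)
  # center of the burst so point targets peak at their true depth
  lag <- channels$burst_s / 2

  Z <- matrix(grid_z, nz, nx)
  X <- matrix(grid_x, nz, nx, byrow = TRUE)
  img <- matrix(0 + 0i, nz, nx)
  for (e in seq_len(geom$n_elements)) {
    if (apod[e] == 0) next
    tau <- plane_wave_delay(Z, X, geom$positions[e], angle, c0) + lag
    idx <- tau * channels$fs + 1
    i0 <- floor(idx)
    frac <- idx - i0
    ok <- i0 >= 1 & i0 < n_samp
    if (f_number > 0) {
      ok <- ok & abs(X - geom$positions[e]) <= Z / (2 * f_number)
    }
    vals <- matrix(0 + 0i, nz, nx)
    vals[ok] <- A[i0[ok], e] * (1 - frac[ok]) + A[i0[ok] + 1, e] * frac[ok]
    # demodulate the carrier phase at the pixel delay
    vals[ok] <- vals[ok] * exp(-2i * pi * channels$center_frequency *
                                 (tau[ok] - lag))
    img <- img + apod[e] * vals
  }
  structure(list(data = img, angle = angle, grid_z = grid_z, grid_x = grid_x),
            class = "angled_image")
}

#' Coherent compounding of angled images
#'
#' Pre-detection (complex) pixel-wise mean of images acquired at different
#' plane-wave tilt angles; constructive summation at true scatterer
#' positions raises contrast and resolution while incoherent sidelobes
#' average down. Compounding N copies of one image returns that image. By
#' the triangle inequality the compounded modulus never exceeds the mean of
#' the input moduli, with equality for phase-aligned inputs.
#'
#' @param images List of `angled_image`s sharing one grid.
#' @return A complex matrix (the compounded frame) with the grid attached
#'   as attributes.
#' @export
coherent_compound <- function(images) {
  stopifnot(is.list(images), length(images) > 0)
  dims <- lapply(images, function(im) dim(im$data))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    abort_param("All angled images must share the same grid.")
  }
  out <- Reduce(`+`, lapply(images, function(im) im$data)) / length(images)
  attr(out, "grid_z") <- images[[1]]$grid_z
  attr(out, "grid_x") <- images[[1]]$grid_x
  attr(out, "angles") <- vapply(images, function(im) im$angle, numeric(1))
  out
}
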