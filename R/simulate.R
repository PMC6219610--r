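#' Pulsatile axial blood velocity waveform
#'
#' Velocity of arterial blood over the cardiac cycle: a raised-cosine
#' systolic pulse riding on a diastolic baseline. The waveform is periodic
#' with period `1 / heart_rate`, attains exactly `v_systolic` at the middle
#' of the systolic upstroke and `v_diastolic` throughout diastole, so its
#' resistivity index is `(v_systolic - v_diastolic) / v_systolic`.
#'
#' @param t Times in seconds (vectorized).
#' @param heart_rate Cardiac frequency in Hz.
#' @param v_systolic Peak (systolic) axial speed in m/s.
#' @param v_diastolic Minimum (diastolic) axial speed in m/s.
#' @param systolic_fraction Fraction of the cycle occupied by the systolic
#'   pulse.
#' @return Axial speed in m/s, same length as `t`.
#' @examples
#' pulsatile_velocity(0.5 * 0.45 / 4, 4, 0.10, 0.04)  # systolic peak: 0.10
#' @export
pulsatile_velocity <- function(t, heart_rate, v_systolic, v_diastolic,
                               systolic_fraction = 0.45) {
  check_positive(heart_rate, "heart_rate")
  if (!is.numeric(v_systolic) || !is.numeric(v_diastolic) ||
      v_diastolic < 0 || v_systolic < v_diastolic) {
    abort_param("Require v_systolic >= v_diastolic >= 0.")
  }
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    abort_param("`systolic_fraction` must be in (0, 1).")
  }
  u <- (t * heart_rate) %% 1
  pulse <- ifelse(u < systolic_fraction,
                  0.5 * (1 - cos(2 * pi * u / systolic_fraction)), 0)
  v_diastolic + (v_systolic - v_diastolic) * pulse
}

#' Random scatterer field for IQ synthesis
#'
#' Draws the tissue and blood scatterer populations that
#' [simulate_iq_block()] turns into a complex IQ data block. Tissue is a
#' per-pixel complex reflectivity image (strong, spatially coherent) that
#' moves as a whole with a slow (< 5 Hz) sinusoidal axial displacement,
#' which makes the tissue contribution to the space-time (Casorati) matrix
#' low-rank, as spatiotemporal clutter filtering assumes. Blood is a sparse
#' population of weak scatterers (Poisson count per pixel) whose axial
#' velocities follow a shared pulsatile waveform with per-scatterer random
#' flow direction and a mild speed jitter; their echo power is the
#' configured margin below tissue.
#'
#' @param config An [acquisition_config()].
#' @param regions A [region_set()] on the same grid (or `NULL` for a single
#'   whole-grid vessel region).
#' @param blood_density Mean blood scatterers per pixel per region, before
#'   the `density_multiplier`.
#' @param density_multiplier Named numeric, per-region multiplicative factor
#'   on `blood_density` (this is how relative CBV enters the simulation:
#'   density scales as `1 + CBV/100`).
#' @param blood_amplitude Echo amplitude of one blood scatterer.
#' @param tissue_to_blood_db Tissue-to-blood pixel power margin in dB.
#' @param noise_to_blood_db Additive-noise-to-blood pixel power margin in dB
#'   (negative: noise below blood).
#' @param heart_rate Cardiac frequency in Hz.
#' @param v_systolic,v_diastolic Pulsatile waveform extrema in m/s (either
#'   scalars or named per-region vectors).
#' @param tissue_motion_amplitude Axial tissue displacement amplitude in m.
#' @param tissue_motion_frequency Tissue motion frequency in Hz (< 5 Hz).
#' @param tissue_motion_jitter Per-frame random axial displacement jitter
#'   (m, standard deviation); nonzero values emulate chest-compression
#'   motion artifacts that raise the effective clutter rank.
#' @param seed Integer seed; the field is fully reproducible given it.
#' @return An object of class `scatterer_field`.
#' @export
scatterer_field <- function(config,
                            regions = NULL,
                            blood_density = 4,
                            density_multiplier = NULL,
                            blood_amplitude = 1,
                            tissue_to_blood_db = 30,
                            noise_to_blood_db = -30,
                            heart_rate = 4,
                            v_systolic = 0.10,
                            v_diastolic = 0.04,
                            tissue_motion_amplitude = 2e-6,
                            tissue_motion_frequency = 1.5,
                            tissue_motion_jitter = 0,
                            seed = 1) {
  stopifnot(inherits(config, "acq_config"))
  nz <- config$grid_shape[1]; nx <- config$grid_shape[2]
  if (is.null(regions)) {
    regions <- structure(list(whole_slice = matrix(TRUE, nz, nx)),
                         class = "region_set", grid_shape = c(nz, nx))
  }
  if (!all(attr(regions, "grid_shape") == c(nz, nx))) {
    abort_param("`regions` grid does not match `config$grid_shape`.")
  }
  vessel_regions <- setdiff(names(regions), "whole_slice")
  if (length(vessel_regions) == 0) vessel_regions <- "whole_slice"
  if (is.null(density_multiplier)) {
    density_multiplier <- stats::setNames(rep(1, length(vessel_regions)),
                                          vessel_regions)
  }
  per_region <- function(x, r) if (length(x) > 1) x[[r]] else x

  set.seed(seed)
  npix <- nz * nx
  # tissue as fully developed speckle: per-pixel circular complex Gaussian
  # reflectivity whose mean pixel power sits the configured margin above
  # the baseline blood pixel power
  ref_density <- if (blood_density > 0) blood_density else 1
  tissue_power <- ref_density * blood_amplitude^2 *
    10^(tissue_to_blood_db / 10)
  tissue_img <- matrix(sqrt(tissue_power / 2) *
                         (stats::rnorm(npix) + 1i * stats::rnorm(npix)),
                       nz, nx)

  blood <- purrr::map_dfr(vessel_regions, function(r) {
    m <- if (r %in% names(density_multiplier)) {
      max(0, density_multiplier[[r]])
    } else if (length(density_multiplier) == 1 &&
               is.null(names(density_multiplier))) {
      max(0, density_multiplier[[1]])
    } else 1
    pix <- which(regions[[r]])
    k <- stats::rpois(1, blood_density * m * length(pix))
    if (k == 0) return(NULL)
    tibble::tibble(
      region = r,
      pixel = sample(pix, k, replace = TRUE),
      sign = sample(c(-1, 1), k, replace = TRUE),
      jitter = stats::runif(k, 0.8, 1.2),
      phase0 = stats::runif(k, 0, 2 * pi),
      v_systolic = per_region(v_systolic, r),
      v_diastolic = per_region(v_diastolic, r)
    )
  })

  noise_sd <- sqrt(ref_density * blood_amplitude^2 *
                     10^(noise_to_blood_db / 10) / 2)

  structure(
    list(
      grid_shape = c(nz, nx),
      tissue_img = tissue_img,
      tissue_motion = list(amplitude = tissue_motion_amplitude,
                           frequency = tissue_motion_frequency,
                           phase = stats::runif(1, 0, 2 * pi),
                           jitter = tissue_motion_jitter),
      blood = blood,
      blood_amplitude = blood_amplitude,
      heart_rate = heart_rate,
      cardiac_phase = stats::runif(1),
      noise_sd = noise_sd,
      seed = seed
    ),
    class = "scatterer_field"
  )
}

#' Synthesize one IQ data block
#'
#' Direct image-domain synthesis of a complex IQ block (depth x lateral x
#' frame). Every scatterer contributes a complex exponential whose phase
#' advances by `4 * pi * f0 * v * dt / c` per frame (two-way pulsed-Doppler
#' convention) where `v` is its instantaneous axial velocity; tissue moves
#' with the field's shared slow sinusoid and blood follows the pulsatile
#' waveform. Complex white noise is added on top. Blocks are reproducible
#' bit-for-bit for a fixed field and `seed`. If any blood speed exceeds half
#' the aliasing-free span the block is flagged (`aliased` attribute) with a
#' warning.
#'
#' @param field A [scatterer_field()].
#' @param config An [acquisition_config()].
#' @param t0 Acquisition start time of the block in seconds (sets the
#'   cardiac phase).
#' @param seed Integer seed for the additive noise.
#' @param frames Number of frames to synthesize (defaults to
#'   `config$frames_per_block`).
#' @return An object of class `iq_block`: complex array plus frame-rate and
#'   pixel-pitch metadata.
#' @export
simulate_iq_block <- function(field, config, t0 = 0, seed = 1,
                              frames = config$frames_per_block) {
  stopifnot(inherits(field, "scatterer_field"), inherits(config, "acq_config"))
  nz <- config$grid_shape[1]; nx <- config$grid_shape[2]
  if (!all(field$grid_shape == c(nz, nx))) {
    abort_param("`field` and `config` disagree on the image grid.")
  }
  fs <- compound_frame_rate(config)
  f0 <- config$center_frequency
  c0 <- config$sound_speed
  nt <- as.integer(frames)
  npix <- nz * nx
  t_frames <- t0 + (seq_len(nt) - 1) / fs
  phase_gain <- 4 * pi * f0 / c0        # rad per meter of axial path

  set.seed(seed)
  # tissue: rank-one space (x) time structure plus optional per-frame jitter
  disp <- field$tissue_motion$amplitude *
    sin(2 * pi * field$tissue_motion$frequency * t_frames +
          field$tissue_motion$phase)
  if (field$tissue_motion$jitter > 0) {
    disp <- disp + cumsum(stats::rnorm(nt, 0, field$tissue_motion$jitter))
  }
  X <- outer(as.vector(field$tissue_img), exp(1i * phase_gain * disp))

  aliased <- FALSE
  if (!is.null(field$blood) && nrow(field$blood) > 0) {
    b <- field$blood
    tc <- t_frames + field$cardiac_phase / field$heart_rate
    span <- max_unaliased_velocity_span(config)
    for (r in unique(b$region)) {
      idx <- which(b$region == r)
      v_sys <- b$v_systolic[idx[1]]; v_dia <- b$v_diastolic[idx[1]]
      if (max(b$jitter[idx]) * v_sys > span / 2 + 1e-12) aliased <- TRUE
      v <- pulsatile_velocity(tc, field$heart_rate, v_sys, v_dia)
      # cumulative axial path shared by the region, scaled per scatterer
      path <- cumsum(v) / fs
      g <- b$sign[idx] * b$jitter[idx]
      E <- exp(1i * (b$phase0[idx] + phase_gain * outer(g, path)))
      X <- X + field$blood_amplitude *
        rowsum_complex(E, b$pixel[idx], npix)
    }
  }
  if (aliased) {
    warning("Blood speeds exceed half the aliasing-free span; block flagged.",
            call. = FALSE)
  }
  if (field$noise_sd > 0) {
    X <- X + field$noise_sd *
      (stats::rnorm(npix * nt) + 1i * stats::rnorm(npix * nt))
  }

  structure(
    list(
      data = array(X, c(nz, nx, nt)),
      fs = fs,
      center_frequency = f0,
      sound_speed = c0,
      pixel_pitch = config$pixel_pitch,
      t0 = t0,
      aliased = aliased
    ),
    class = "iq_block"
  )
}

#' @export
print.iq_block <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<iq_block> %d x %d px, %d frames at %g Hz (%.3g s), t0 = %.3g s%s\n",
    d[1], d[2], d[3], x$fs, d[3] / x$fs, x$t0,
    if (isTRUE(x$aliased)) " [aliased]" else ""))
  invisible(x)
}
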