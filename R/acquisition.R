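#' Ultrafast plane-wave acquisition configuration
#'
#' Describes one ultrafast Doppler acquisition: a linear array transmitting
#' tilted plane waves that are coherently compounded into one frame per
#' angle cycle. The defaults reproduce a 6.4 MHz sequence firing 4 plane
#' waves (tilted -3, -1, 1, 3 degrees) at an 8 kHz pulse repetition
#' frequency, so the compounded frame rate is 2 kHz and a 1000-frame block
#' spans 0.5 s.
#'
#' @param center_frequency Transducer center frequency in Hz.
#' @param sound_speed Speed of sound in m/s.
#' @param pulse_repetition_frequency Plane-wave firing rate in Hz.
#' @param tilt_angles Plane-wave tilt angles in degrees; one compounded
#'   frame is formed per sweep through all angles.
#' @param frames_per_block Compounded frames per Doppler block.
#' @param block_interval Seconds between successive Doppler blocks.
#' @param pixel_pitch Length-2 numeric, axial and lateral pixel pitch in m.
#' @param grid_shape Length-2 integer, image grid size as (depth, lateral)
#'   pixel counts.
#'
#' @return An object of class `acq_config` (a validated list).
#' @examples
#' cfg <- acquisition_config()
#' compound_frame_rate(cfg)  # 2000 Hz
#' @export
acquisition_config <- function(center_frequency = 6.4e6,
                               sound_speed = 1540,
                               pulse_repetition_frequency = 8000,
                               tilt_angles = c(-3, -1, 1, 3),
                               frames_per_block = 1000,
                               block_interval = 10,
                               pixel_pitch = c(1e-4, 1e-4),
                               grid_shape = c(64L, 64L)) {
  check_positive(center_frequency, "center_frequency")
  check_positive(sound_speed, "sound_speed")
  check_positive(pulse_repetition_frequency, "pulse_repetition_frequency")
  if (length(tilt_angles) < 1L || !is.numeric(tilt_angles)) {
    abort_param("`tilt_angles` must be a non-empty numeric vector.")
  }
  check_positive(frames_per_block, "frames_per_block")
  check_positive(block_interval, "block_interval")
  if (length(pixel_pitch) != 2L || any(!is.finite(pixel_pitch)) ||
      any(pixel_pitch <= 0)) {
    abort_param("`pixel_pitch` must be two positive numbers (axial, lateral).")
  }
  if (length(grid_shape) != 2L || any(grid_shape < 1)) {
    abort_param("`grid_shape` must be two positive integers (depth, lateral).")
  }
  structure(
    list(
      center_frequency = center_frequency,
      sound_speed = sound_speed,
      pulse_repetition_frequency = pulse_repetition_frequency,
      n_angles = length(tilt_angles),
      tilt_angles = tilt_angles,
      frames_per_block = as.integer(frames_per_block),
      block_interval = block_interval,
      pixel_pitch = pixel_pitch,
      grid_shape = as.integer(grid_shape)
    ),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat("<acq_config>\n")
  cat(sprintf("  f0 %.2f MHz, c %g m/s, PRF %g Hz, %d angles (%s deg)\n",
              x$center_frequency / 1e6, x$sound_speed,
              x$pulse_repetition_frequency, x$n_angles,
              paste(x$tilt_angles, collapse = ", ")))
  cat(sprintf("  compounded rate %g Hz, %d frames/block (%.3g s), every %g s\n",
              compound_frame_rate(x), x$frames_per_block,
              x$frames_per_block / compound_frame_rate(x), x$block_interval))
  cat(sprintf("  grid %d x %d px, pitch %.3g x %.3g mm\n",
              x$grid_shape[1], x$grid_shape[2],
              x$pixel_pitch[1] * 1e3, x$pixel_pitch[2] * 1e3))
  invisible(x)
}

#' Compounded frame rate of an acquisition
#'
#' One compounded frame requires one transmission per tilt angle, so the
#' frame rate after coherent compounding is the pulse repetition frequency
#' divided by the number of angles (8 kHz / 4 angles = 2 kHz).
#'
#' @param config An [acquisition_config()].
#' @return Frame rate in Hz.
#' @export
compound_frame_rate <- function(config) {
  stopifnot(inherits(config, "acq_config"))
  config$pulse_repetition_frequency / config$n_angles
}

#' Aliasing-free axial velocity span
#'
#' Full (peak-to-peak) span of axial blood velocities that can be sampled
#' without aliasing: `c * fs / (2 * f0)` where `fs` is the compounded frame
#' rate. At 2 kHz and 6.4 MHz in soft tissue this is 0.2406 m/s, i.e. the
#' sequence samples flows below about 24 cm/s; signed velocities are
#' unambiguous within plus or minus half the span.
#'
#' @inheritParams compound_frame_rate
#' @return Velocity span in m/s.
#' @export
max_unaliased_velocity_span <- function(config) {
  stopifnot(inherits(config, "acq_config"))
  fs <- compound_frame_rate(config)
  config$sound_speed * fs / (2 * config$center_frequency)
}

#' Duration of one Doppler block
#'
#' @inheritParams compound_frame_rate
#' @return Seconds spanned by one block of compounded frames.
#' @export
block_duration <- function(config) {
  stopifnot(inherits(config, "acq_config"))
  config$frames_per_block / compound_frame_rate(config)
}
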