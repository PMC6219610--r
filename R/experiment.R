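#' Generate a synthetic cohort of ultrafast Doppler experiments
#'
#' Builds `n_subjects` full experiment series from a group template: one
#' Doppler block per `block_interval_s` over the protocol timeline, each
#' block's blood scatterer density per region scaling as
#' `1 + relativeCBV(t) / 100`, cardiac pulsatility following the template's
#' time-varying resistivity index, and chest-compression motion artifacts in
#' the template's artifact window. Subject-level biological variation enters
#' as one global multiplicative factor on every CBV curve (SD from the
#' reported whole-slice dispersion) plus an extra hippocampal factor, and as
#' a MAP offset. The realized per-subject curves, MAP trace and artifact
#' flags are stored as ground truth alongside the block recipes.
#'
#' Blocks are not materialized up front (a 90-minute series of complex
#' cubes would not fit in memory); [series_block()] synthesizes any block
#' reproducibly from its stored recipe, and [power_map_series()] streams
#' over them.
#'
#' The background (non-cortex/hippocampus/thalamus) curve is solved per
#' subject so that the area-weighted mix of regional curves reproduces the
#' subject's whole-slice curve exactly; both the regional and the
#' whole-slice template contracts then hold simultaneously.
#'
#' @param template A [hemodynamic_template()].
#' @param config An [acquisition_config()].
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer master seed; everything derives from it.
#' @param regions A [region_set()] on the config grid.
#' @param block_interval_s Seconds between blocks; defaults to the
#'   template's protocol value (6 s sham, 10 s arrest groups).
#' @param baseline_interval_s Seconds between blocks inside the baseline
#'   phase; defaults to `block_interval_s`. Desk-scale runs that thin the
#'   protocol keep a denser baseline here because the per-pixel baseline
#'   mean is the denominator of every relative-CBV value, and a short
#'   baseline biases the ratio upward.
#' @param blood_density Baseline blood scatterers per pixel.
#' @param ... Further arguments passed to [scatterer_field()] (power
#'   margins, motion parameters).
#' @return A list of `experiment_series` objects.
#' @export
make_experiment <- function(template, config, n_subjects = 5, seed = 1,
                            regions = region_set(config$grid_shape),
                            block_interval_s = template$block_interval_s,
                            baseline_interval_s = block_interval_s,
                            blood_density = 4, ...) {
  stopifnot(inherits(template, "hemo_template"),
            inherits(config, "acq_config"))
  if (n_subjects < 1) abort_param("`n_subjects` must be >= 1.")
  if (!all(attr(regions, "grid_shape") == config$grid_shape)) {
    abort_param("`regions` grid does not match `config$grid_shape`.")
  }
  needed <- c("cortex", "hippocampus", "thalamus", "background")
  if (!all(needed %in% names(regions))) {
    abort_param("`regions` must contain cortex, hippocampus, thalamus and background masks.")
  }

  times <- seq(template$t_range[1], template$t_range[2],
               by = block_interval_s / 60)
  if (baseline_interval_s < block_interval_s) {
    base <- template$events[template$events$phase == "baseline", ]
    times <- sort(unique(c(times, seq(base$start_min, base$end_min,
                                      by = baseline_interval_s / 60))))
  }
  n_blocks <- length(times)
  seeds <- matrix(derive_seeds(seed, n_subjects * (n_blocks + 3)),
                  nrow = n_subjects)
  sd <- template$subject_sd
  w <- vapply(needed, function(r) mean(regions[[r]]), numeric(1))

  purrr::map(seq_len(n_subjects), function(s) {
    set.seed(seeds[s, 1])
    g <- max(0.05, stats::rnorm(1, 1, sd$global))
    h <- max(0.05, stats::rnorm(1, 1, sd$hippocampus_extra))
    cf <- max(0.05, stats::rnorm(1, 1, sd$cortex_extra %||% 0))
    tf <- max(0.05, stats::rnorm(1, 1, sd$thalamus_extra %||% 0))
    map_offset <- stats::rnorm(1, 0, sd$map_offset)

    curves <- list(
      whole_slice = g * template_cbv(template, "whole_slice", times),
      cortex = g * cf * template_cbv(template, "cortex", times),
      hippocampus = g * h * template_cbv(template, "hippocampus", times),
      thalamus = g * tf * template_cbv(template, "thalamus", times)
    )
    curves$background <- (curves$whole_slice -
                            w["cortex"] * curves$cortex -
                            w["hippocampus"] * curves$hippocampus -
                            w["thalamus"] * curves$thalamus) / w["background"]

    map_trace <- template_map(template, times) + map_offset +
      stats::rnorm(n_blocks, 0, sd$map_noise)
    if (!is.null(template$map_coupling)) {
      # passive pressure-flow coupling: the subject's own CBV course drives
      # its post-resuscitation MAP
      cp <- template$map_coupling
      post <- times >= cp$from_min
      map_trace[post] <- cp$base + cp$slope_per_pct *
        curves$whole_slice[post] + map_offset +
        stats::rnorm(sum(post), 0, sd$map_noise)
    }
    if (template$group %in% c("control", "tlv")) {
      post <- times >= 2
      map_trace[post] <- pmin(pmax(map_trace[post], 60), 90)
    }

    artifact <- if (is.null(template$artifact_window)) {
      rep(FALSE, n_blocks)
    } else {
      times >= template$artifact_window[1] & times <= template$artifact_window[2]
    }

    ri_t <- template_ri(template, times)
    v_sys_t <- template$v_systolic * template_velocity_scale(template, times)

    structure(
      list(
        subject = s,
        group = template$group,
        times_min = times,
        config = config,
        regions = regions,
        blood_density = blood_density,
        field_args = list(...),
        multipliers = lapply(stats::setNames(nm = needed),
                             function(r) pmax(0.02, 1 + curves[[r]] / 100)),
        v_systolic = v_sys_t,
        v_diastolic = v_sys_t * (1 - ri_t),
        heart_rate = template$heart_rate,
        artifact = artifact,
        map = tibble::tibble(time_min = times, map_mmHg = map_trace),
        ground_truth = list(curves = curves, global_factor = g,
                            hippocampus_factor = h, cortex_factor = cf,
                            thalamus_factor = tf, map_offset = map_offset),
        block_seeds = seeds[s, -(1:3)],
        template_group = template$group
      ),
      class = "experiment_series"
    )
  })
}

#' @export
print.experiment_series <- function(x, ...) {
  cat(sprintf(
    "<experiment_series> subject %d (%s), %d blocks every %g s, t in [%g, %g] min\n",
    x$subject, x$group, length(x$times_min),
    diff(x$times_min[1:2]) * 60, min(x$times_min), max(x$times_min)))
  invisible(x)
}

#' Ground-truth regional series of a subject
#'
#' The per-subject realized template curves in the same long format as
#' [regional_series()], optionally with measurement-level noise added.
#' Useful for curve-level analyses (group statistics, autoregulation
#' clouds) without synthesizing and filtering IQ data, and as the reference
#' the full pipeline is validated against.
#'
#' @param series An `experiment_series`.
#' @param cbv_noise_sd SD (in %) of additive noise emulating the
#'   measurement scatter of the Doppler estimates; 0 returns the clean
#'   curves.
#' @param seed Seed for the noise.
#' @return A tibble with `subject`, `group`, `time_min`, `region`,
#'   `value_pct`, `artifact`.
#' @export
ground_truth_series <- function(series, cbv_noise_sd = 0, seed = 1) {
  stopifnot(inherits(series, "experiment_series"))
  set.seed(seed + series$subject)
  regions <- c("whole_slice", "cortex", "hippocampus", "thalamus")
  purrr::map_dfr(regions, function(r) {
    v <- series$ground_truth$curves[[r]]
    tibble::tibble(
      subject = series$subject, group = series$group,
      time_min = series$times_min, region = r,
      value_pct = v + stats::rnorm(length(v), 0, cbv_noise_sd),
      artifact = series$artifact
    )
  })
}

#' Synthesize one block of an experiment series
#'
#' Realizes block `i` of a series from its stored recipe: scatterer
#' densities at the block's time, pulsatility of that protocol phase, and
#' chest-compression motion jitter inside the artifact window. Bit-identical
#' across calls for the same series.
#'
#' @param series An `experiment_series` from [make_experiment()].
#' @param i Block index.
#' @param frames Frames to synthesize (default the config's
#'   `frames_per_block`).
#' @return An `iq_block`.
#' @export
series_block <- function(series, i, frames = series$config$frames_per_block) {
  stopifnot(inherits(series, "experiment_series"))
  if (i < 1 || i > length(series$times_min)) abort_param("Block index out of range.")
  mult <- vapply(series$multipliers, `[`, numeric(1), i)
  args <- c(
    list(config = series$config, regions = series$regions,
         blood_density = series$blood_density,
         density_multiplier = mult,
         heart_rate = series$heart_rate,
         v_systolic = series$v_systolic[i],
         v_diastolic = series$v_diastolic[i],
         seed = series$block_seeds[i]),
    series$field_args
  )
  if (series$artifact[i]) {
    args$tissue_motion_jitter <- 2e-7
    args$tissue_motion_amplitude <- 8 *
      (args$tissue_motion_amplitude %||% 2e-6)
  }
  field <- do.call(scatterer_field, args)
  simulate_iq_block(field, series$config, t0 = series$times_min[i] * 60,
                    seed = series$block_seeds[i] + 1L, frames = frames)
}

#' Stream a series into power-Doppler maps
#'
#' Synthesizes every block of a series, clutter-filters it with the given
#' SVD specification and reduces it to a power-Doppler map, keeping only
#' the maps in memory.
#'
#' @param series An `experiment_series`.
#' @param spec An [svd_filter_spec()].
#' @param frames Frames per block (reduced counts speed up desk-scale
#'   runs).
#' @return A list of class `power_map_series`: `maps` (list of power
#'   `parametric_map`s), `times_min`, `artifact`, plus the subject/group
#'   labels.
#' @export
power_map_series <- function(series, spec = svd_filter_spec(),
                             frames = series$config$frames_per_block) {
  stopifnot(inherits(series, "experiment_series"))
  maps <- purrr::map(seq_along(series$times_min), function(i) {
    blk <- series_block(series, i, frames = frames)
    flt <- svd_filter(blk, spec)
    m <- power_doppler(flt)
    m$time_min <- series$times_min[i]
    m
  })
  structure(list(maps = maps, times_min = series$times_min,
                 artifact = series$artifact, subject = series$subject,
                 group = series$group, map = series$map,
                 ground_truth = series$ground_truth),
            class = "power_map_series")
}
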