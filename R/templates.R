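#' Group hemodynamic template
#'
#' Ground-truth time courses used by the synthetic-data generator for the
#' three study arms of a cardiac-arrest / resuscitation protocol:
#'
#' * `control`: asphyxial cardiac arrest and resuscitation at physiological
#'   temperature. The whole-slice relative CBV curve peaks at +150% about
#'   10 min after CPR; the hippocampal curve is scaled to peak at +210%,
#'   the thalamic one at +126.6%. Post-resuscitation MAP sits near 78 mmHg,
#'   inside the 60-90 mmHg physiological band.
#' * `tlv`: same arrest, followed by rapid cooling through total liquid
#'   ventilation. Hyperemia is mitigated: every regional curve stays at or
#'   below its control counterpart throughout the 7-37 min analysis window
#'   (whole-slice time-normalized AUC about +26%), the hippocampus briefly
#'   reaching +100%. Post-resuscitation MAP tracks the CBV course around
#'   62-66 mmHg, giving the preserved linear CBV-MAP coupling of that arm.
#' * `sham`: no arrest; a 10-minute session with 4 min of baseline followed
#'   by a slow aortic-compression MAP sweep (about 58-138 mmHg). CBV follows
#'   an autoregulation plateau response, so relative CBV stays within a few
#'   tens of percent across the whole sweep.
#'
#' Times are minutes relative to CPR start (t = 0) for the arrest groups and
#' minutes from session start for sham. Curves are stored as piecewise-linear
#' knots; the baseline segment of every relative-CBV curve is 0%. Cardiac
#' pulsatility is parameterized by a heart rate (default 4 Hz, i.e. two
#' cardiac cycles per 0.5 s block), a systolic velocity scale and a
#' time-varying resistivity index (vasodilation during hyperemia lowers RI in
#' the control arm). The arrest groups carry a motion-artifact window at
#' 23-26 min emulating chest-compression artifacts.
#'
#' @param group One of `"control"`, `"tlv"`, `"sham"`.
#' @param heart_rate Cardiac frequency in Hz.
#' @param v_systolic Baseline systolic axial blood speed in m/s.
#' @return An object of class `hemo_template`.
#' @examples
#' tpl <- hemodynamic_template("control")
#' template_cbv(tpl, "hippocampus", 10)  # +210
#' @export
hemodynamic_template <- function(group = c("control", "tlv", "sham"),
                                 heart_rate = 4,
                                 v_systolic = 0.10) {
  group <- match.arg(group)
  check_positive(heart_rate, "heart_rate")
  check_positive(v_systolic, "v_systolic")

  arrest_ws <- function(values) {
    tibble::tibble(
      time_min = c(-23, -13, -12, -9, -5, 0, 2, 4, 7, 10, 14, 22, 26,
                   30, 37, 45, 55, 60, 67),
      value_pct = values
    )
  }

  map_coupling <- NULL
  if (group == "control") {
    ws <- arrest_ws(c(0, 0, 10, -70, -85, -85, -30, 10, 55, 150, 115, 85,
                      72, 62, 48, 40, 28, 22, 18))
    region_scale <- c(whole_slice = 1, cortex = 1,
                      hippocampus = 210 / 150, thalamus = 126.6 / 150)
    map_knots <- tibble::tibble(
      time_min = c(-23, -18, -13, -12, -10, -8, -5, 0, 1, 2, 4, 7, 12, 20,
                   26, 30, 37, 45, 55, 60, 67),
      map_mmHg = c(70, 72, 71, 86, 55, 25, 12, 10, 55, 75, 80, 78, 80, 76,
                   79, 78, 77, 79, 77, 78, 78)
    )
    ri_knots <- tibble::tibble(
      time_min = c(-23, -13, -12, -8, 0, 4, 7, 10, 16, 22, 30, 37, 67),
      ri = c(0.6, 0.6, 0.62, 0.7, 0.7, 0.5, 0.4, 0.32, 0.35, 0.4, 0.5,
             0.55, 0.6)
    )
    vel_knots <- tibble::tibble(
      time_min = c(-23, -13, -12, -9, -5, 0, 2, 7, 10, 37, 67),
      scale = c(1, 1, 1, 0.5, 0.15, 0.12, 0.8, 1, 1, 1, 1)
    )
    subject_sd <- list(global = 34 / 150,
                       hippocampus_extra = sqrt((74 / 210)^2 - (34 / 150)^2),
                       cortex_extra = 0.45, thalamus_extra = 0.7,
                       map_offset = 3, cbv_noise = 3, map_noise = 1.5)
    artifact_window <- c(23, 26)
    t_range <- c(-23, 67)
    block_interval_s <- 10
    events <- tibble::tibble(
      phase = c("baseline", "asphyxia", "cpr", "follow_up"),
      start_min = c(-23, -13, 0, 2), end_min = c(-13, 0, 2, 67)
    )
  } else if (group == "tlv") {
    ws <- arrest_ws(c(0, 0, 10, -70, -85, -85, -40, -10, 15, 45, 50, 25,
                      20, 15, 10, 8, 5, 4, 3))
    # extra knots sharpening the brief +100% hippocampal excursion
    ws <- dplyr::bind_rows(ws, tibble::tibble(time_min = c(12, 16),
                                              value_pct = c(50, 35))) |>
      dplyr::distinct(.data$time_min, .keep_all = TRUE) |>
      dplyr::arrange(.data$time_min)
    # mitigation is partial and region-dependent: weakest in the cortex,
    # strongest in the thalamus, brief +100% excursion in the hippocampus
    region_scale <- c(whole_slice = 1, cortex = 1.6,
                      hippocampus = 2.0, thalamus = 1.4)
    cbv_at <- function(t) stats::approx(ws$time_min, ws$value_pct, t,
                                        rule = 2)$y
    post_t <- c(2, 4, 7, 10, 12, 16, 22, 26, 30, 37, 45, 55, 60, 67)
    map_knots <- tibble::tibble(
      time_min = c(-23, -18, -13, -12, -10, -8, -5, 0, 1, post_t),
      map_mmHg = c(70, 71, 70, 85, 54, 24, 12, 10, 45,
                   pmax(60.5, 62 + 0.08 * cbv_at(post_t)))
    )
    ri_knots <- tibble::tibble(
      time_min = c(-23, -13, -12, -8, 0, 4, 10, 37, 67),
      ri = c(0.6, 0.6, 0.62, 0.7, 0.7, 0.6, 0.55, 0.58, 0.6)
    )
    vel_knots <- tibble::tibble(
      time_min = c(-23, -13, -12, -9, -5, 0, 2, 7, 10, 37, 67),
      scale = c(1, 1, 1, 0.5, 0.15, 0.12, 0.7, 1, 1, 1, 1)
    )
    subject_sd <- list(global = 0.5, hippocampus_extra = 0.3,
                       cortex_extra = 0.45, thalamus_extra = 0.7,
                       map_offset = 1, cbv_noise = 3, map_noise = 0.5)
    # post-resuscitation MAP passively coupled to the subject's CBV course
    # (autoregulation lost but pressure-flow coupling preserved under TLV)
    map_coupling <- list(base = 62, slope_per_pct = 0.08, from_min = 2)
    artifact_window <- c(23, 26)
    t_range <- c(-23, 67)
    block_interval_s <- 10
    events <- tibble::tibble(
      phase = c("baseline", "asphyxia", "cpr", "tlv", "follow_up"),
      start_min = c(-23, -13, 0, 1, 31), end_min = c(-13, 0, 2, 31, 67)
    )
  } else {
    map_knots <- tibble::tibble(
      time_min = c(0, 4, 4.8, 5.5, 6.2, 7, 8, 9, 9.6, 10),
      map_mmHg = c(72, 72, 62, 58, 75, 92, 112, 132, 138, 80)
    )
    # autoregulation plateau: CBV response to MAP, nearly flat in the
    # physiological range, collapsing below ~60 mmHg
    response <- tibble::tibble(map_mmHg = c(40, 60, 70, 105, 120, 140),
                               value_pct = c(-12, -3, 0, 5, 10, 14))
    tt <- seq(0, 10, by = 0.1)
    mp <- stats::approx(map_knots$time_min, map_knots$map_mmHg, tt,
                        rule = 2)$y
    ws <- tibble::tibble(
      time_min = tt,
      value_pct = stats::approx(response$map_mmHg, response$value_pct, mp,
                                rule = 2)$y
    )
    ws$value_pct <- ws$value_pct - mean(ws$value_pct[tt <= 4])
    region_scale <- c(whole_slice = 1, cortex = 1, hippocampus = 1,
                      thalamus = 1)
    ri_knots <- tibble::tibble(time_min = c(0, 10), ri = c(0.6, 0.6))
    vel_knots <- tibble::tibble(time_min = c(0, 10), scale = c(1, 1))
    subject_sd <- list(global = 0.1, hippocampus_extra = 0,
                       cortex_extra = 0, thalamus_extra = 0,
                       map_offset = 3, cbv_noise = 2.5, map_noise = 1.5)
    artifact_window <- NULL
    t_range <- c(0, 10)
    block_interval_s <- 6
    events <- tibble::tibble(
      phase = c("baseline", "map_manipulation"),
      start_min = c(0, 4), end_min = c(4, 10)
    )
  }

  cbv_knots <- purrr::map_dfr(names(region_scale), function(r) {
    tibble::tibble(region = r, time_min = ws$time_min,
                   value_pct = ws$value_pct * region_scale[[r]])
  })

  tpl <- structure(
    list(
      group = group,
      cbv_knots = cbv_knots,
      region_scale = region_scale,
      map_knots = map_knots,
      ri_knots = ri_knots,
      vel_knots = vel_knots,
      heart_rate = heart_rate,
      v_systolic = v_systolic,
      subject_sd = subject_sd,
      map_coupling = map_coupling,
      artifact_window = artifact_window,
      t_range = t_range,
      block_interval_s = block_interval_s,
      events = events
    ),
    class = "hemo_template"
  )
  validate_template(tpl)
  tpl
}

validate_template <- function(tpl) {
  base <- tpl$events[tpl$events$phase == "baseline", ]
  tt <- seq(base$start_min, base$end_min, length.out = 21)
  for (r in unique(tpl$cbv_knots$region)) {
    v <- template_cbv(tpl, r, tt)
    if (max(abs(v)) > 1e-6) {
      abort_param(sprintf("Baseline CBV segment of region '%s' is not 0%%.", r))
    }
  }
  if (tpl$group %in% c("control", "tlv")) {
    post <- tpl$map_knots[tpl$map_knots$time_min >= 2, ]
    if (any(post$map_mmHg < 60 | post$map_mmHg > 90)) {
      abort_param("Post-resuscitation MAP must stay within 60-90 mmHg.")
    }
  }
  invisible(tpl)
}

knot_interp <- function(knots, xcol, ycol, x) {
  stats::approx(knots[[xcol]], knots[[ycol]], x, rule = 2, ties = "ordered")$y
}

#' Evaluate template curves
#'
#' Piecewise-linear evaluation of a template's relative-CBV curve for one
#' region (`template_cbv`), its MAP course (`template_map`), its resistivity
#' index course (`template_ri`), and its blood-velocity scale
#' (`template_velocity_scale`).
#'
#' @param template A [hemodynamic_template()].
#' @param region Region name present in the template.
#' @param time_min Times in minutes (relative to CPR start for arrest arms).
#' @return Numeric vector of the same length as `time_min`.
#' @export
template_cbv <- function(template, region, time_min) {
  stopifnot(inherits(template, "hemo_template"))
  k <- template$cbv_knots[template$cbv_knots$region == region, ]
  if (nrow(k) == 0) {
    abort_param(sprintf("Template has no region '%s'.", region))
  }
  knot_interp(k, "time_min", "value_pct", time_min)
}

#' @rdname template_cbv
#' @export
template_map <- function(template, time_min) {
  stopifnot(inherits(template, "hemo_template"))
  knot_interp(template$map_knots, "time_min", "map_mmHg", time_min)
}

#' @rdname template_cbv
#' @export
template_ri <- function(template, time_min) {
  stopifnot(inherits(template, "hemo_template"))
  knot_interp(template$ri_knots, "time_min", "ri", time_min)
}

#' @rdname template_cbv
#' @export
template_velocity_scale <- function(template, time_min) {
  stopifnot(inherits(template, "hemo_template"))
  knot_interp(template$vel_knots, "time_min", "scale", time_min)
}

#' @export
print.hemo_template <- function(x, ...) {
  cat(sprintf("<hemo_template> group '%s', t in [%g, %g] min, block every %g s\n",
              x$group, x$t_range[1], x$t_range[2], x$block_interval_s))
  pk <- vapply(names(x$region_scale), function(r) {
    max(template_cbv(x, r, seq(x$t_range[1], x$t_range[2], by = 0.25)))
  }, numeric(1))
  cat("  peak relative CBV (%):",
      paste(sprintf("%s %.0f", names(pk), pk), collapse = ", "), "\n")
  invisible(x)
}
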