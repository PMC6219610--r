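#' Parametric map container
#'
#' A 2-D parametric image derived from one Doppler block: power Doppler
#' (linear units, nonnegative, proportional to cerebral blood volume),
#' relative CBV (% change versus baseline) or resistivity (dimensionless in
#' \[0, 1\]). Pixels where the quantity is undefined (masked baseline,
#' invalid resistivity) are `NA` and excluded from regional statistics.
#'
#' @param values Numeric matrix.
#' @param kind `"power"`, `"relative_cbv"` or `"resistivity"`.
#' @param time_min Acquisition time in minutes (protocol clock), or `NA`.
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(values,
                           kind = c("power", "relative_cbv", "resistivity"),
                           time_min = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values))
  units <- switch(kind, power = "", relative_cbv = "%", resistivity = "")
  if (kind == "power" && any(values < 0, na.rm = TRUE)) {
    abort_param("Power maps must be nonnegative.")
  }
  if (kind == "resistivity" &&
      any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE)) {
    abort_param("Resistivity maps must lie in [0, 1] where defined.")
  }
  structure(list(values = values, kind = kind, units = units,
                 time_min = time_min),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %s [%s], %d x %d px, t = %s min, %d NA px\n",
              x$kind, x$units, nrow(x$values), ncol(x$values),
              format(x$time_min), sum(is.na(x$values))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parametric map into a long tibble
#'
#' @param x A `parametric_map`.
#' @param ... Unused.
#' @return A tibble with columns `depth_px`, `lateral_px`, `value`, `kind`,
#'   `time_min`.
#' @method tidy parametric_map
#' @export
tidy.parametric_map <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    depth_px = rep(seq_len(d[1]), times = d[2]),
    lateral_px = rep(seq_len(d[2]), each = d[1]),
    value = as.vector(x$values),
    kind = x$kind,
    time_min = x$time_min
  )
}

#' Power Doppler map of a filtered block
#'
#' Per-pixel signal energy of a clutter-filtered IQ block: the mean over
#' frames of the squared modulus. Intensity is proportional to the blood
#' volume sampled in the pixel. Accepts either an `iq_block` (assumed
#' already filtered, or the caller accepts clutter bias) or the result of
#' [svd_filter()].
#'
#' @param x An `iq_block` or `svd_filtered_block`.
#' @return A `parametric_map` of kind `"power"`.
#' @export
power_doppler <- function(x) {
  if (inherits(x, "svd_filtered_block")) x <- x$block
  stopifnot(inherits(x, "iq_block"))
  d <- dim(x$data)
  if (any(d == 0)) abort_param("Block is empty.")
  P <- matrix(rowMeans(matrix(Mod(x$data)^2, d[1] * d[2], d[3])), d[1], d[2])
  parametric_map(P, "power", time_min = x$t0 / 60)
}

#' Per-pixel baseline power reference
#'
#' Averages power maps over the baseline window (default the 10-minute
#' pre-arrest period, -23 to -13 min on the protocol clock) to form the
#' denominator of relative CBV maps. Pixels whose baseline power does not
#' exceed `noise_floor` are masked: relative values there are undefined and
#' excluded from regional averages. Group analyses should use several
#' baseline blocks; a single-block reference is accepted but flagged.
#'
#' @param maps List of power `parametric_map`s.
#' @param times_min Acquisition times of `maps` in minutes; defaults to
#'   their own `time_min` fields.
#' @param window Length-2 numeric, baseline window in minutes.
#' @param noise_floor Power level at or below which a pixel is masked.
#' @return An object of class `baseline_reference`.
#' @export
baseline_reference <- function(maps, times_min = NULL, window = c(-23, -13),
                               noise_floor = 0) {
  stopifnot(is.list(maps), length(maps) > 0)
  if (is.null(times_min)) {
    times_min <- vapply(maps, function(m) m$time_min, numeric(1))
  }
  if (window[1] >= window[2]) abort_param("Baseline window is inverted.")
  keep <- which(times_min >= window[1] & times_min <= window[2])
  if (length(keep) == 0) {
    abort_param("No blocks fall inside the baseline window.")
  }
  if (length(keep) == 1) {
    warning("Baseline reference built from a single block.", call. = FALSE)
  }
  B <- Reduce(`+`, lapply(maps[keep], function(m) m$values)) / length(keep)
  mask <- !(B > noise_floor)
  structure(list(values = B, mask = mask, window = window,
                 n_blocks = length(keep), noise_floor = noise_floor),
            class = "baseline_reference")
}

#' Relative cerebral blood volume map
#'
#' Percent change of power Doppler versus the baseline reference:
#' `100 * (power - baseline) / baseline`. 0% means unchanged blood volume,
#' +150% means 2.5x the baseline level. Pixels masked in the reference
#' (zero, negative or sub-noise baseline) are `NA`.
#'
#' @param map A power `parametric_map`.
#' @param ref A [baseline_reference()].
#' @return A `parametric_map` of kind `"relative_cbv"` in %.
#' @export
relative_cbv <- function(map, ref) {
  stopifnot(inherits(map, "parametric_map"), inherits(ref, "baseline_reference"))
  if (map$kind != "power") abort_param("`map` must be a power map.")
  if (!all(dim(map$values) == dim(ref$values))) {
    abort_param("Map and baseline grids differ.")
  }
  R <- 100 * (map$values - ref$values) / ref$values
  R[ref$mask] <- NA_real_
  parametric_map(R, "relative_cbv", time_min = map$time_min)
}
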