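#' Spatial average of a parametric map over a region
#'
#' Mean of the defined (non-`NA`) pixel values under a boolean mask.
#' A region whose pixels are all undefined yields `NA` with a warning.
#'
#' @param map A `parametric_map` (or bare numeric matrix).
#' @param mask Logical matrix of the same dimensions.
#' @return Scalar mean in the map's units.
#' @export
spatial_average <- function(map, mask) {
  values <- if (inherits(map, "parametric_map")) map$values else map
  stopifnot(is.matrix(values), is.logical(mask))
  if (!all(dim(values) == dim(mask))) abort_param("Map and mask grids differ.")
  if (!any(mask)) abort_param("Mask is empty.")
  v <- values[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    warning("All pixels in the region are undefined.", call. = FALSE)
    return(NA_real_)
  }
  mean(v)
}

#' Regional relative-CBV time series of one subject
#'
#' Turns a streamed power-map series into the per-region relative UfD time
#' series used for hyperemia quantification: a per-pixel baseline reference
#' is built over the baseline window, every block is normalized to a
#' relative-CBV map, and each map is spatially averaged over each requested
#' region mask.
#'
#' @param pm_series A `power_map_series` from [power_map_series()].
#' @param regions A [region_set()]; the analysis regions (defaults to the
#'   four named masks).
#' @param baseline_window Length-2 numeric in minutes.
#' @param noise_floor Baseline power mask level (see
#'   [baseline_reference()]).
#' @return A tibble with columns `subject`, `group`, `time_min`, `region`,
#'   `value_pct`, `artifact`.
#' @export
regional_series <- function(pm_series, regions,
                            baseline_window = c(-23, -13),
                            noise_floor = 0) {
  stopifnot(inherits(pm_series, "power_map_series"))
  ref <- baseline_reference(pm_series$maps, pm_series$times_min,
                            window = baseline_window,
                            noise_floor = noise_floor)
  use_regions <- intersect(
    c("whole_slice", "cortex", "hippocampus", "thalamus"), names(regions))
  if (length(use_regions) == 0) use_regions <- names(regions)
  purrr::map_dfr(seq_along(pm_series$maps), function(i) {
    rel <- relative_cbv(pm_series$maps[[i]], ref)
    tibble::tibble(
      subject = pm_series$subject,
      group = pm_series$group,
      time_min = pm_series$times_min[i],
      region = use_regions,
      value_pct = vapply(use_regions, function(r) {
        spatial_average(rel, regions[[r]])
      }, numeric(1)),
      artifact = pm_series$artifact[i]
    )
  })
}

#' Time-normalized area under a relative UfD curve
#'
#' Trapezoidal integral of the relative UfD series over
#' `[t_start, t_end]`, divided by the window length, so a constant c%
#' series yields c and values are comparable across windows. The series is
#' linearly interpolated at the window bounds; points flagged as artifacts
#' (e.g. chest-compression motion, 23-26 min) are excluded before
#' integration.
#'
#' @param series Data frame with columns `time_min`, `value_pct` and
#'   optionally `artifact` (logical).
#' @param t_start,t_end Window bounds in minutes; must lie within the
#'   series support.
#' @return Time-averaged relative UfD in %.
#' @examples
#' s <- tibble::tibble(time_min = c(7, 37), value_pct = c(0, 100))
#' normalized_auc(s, 7, 37)  # 50
#' @export
normalized_auc <- function(series, t_start, t_end) {
  stopifnot(is.data.frame(series),
            all(c("time_min", "value_pct") %in% names(series)))
  if (t_start >= t_end) abort_param("Require t_start < t_end.")
  if ("artifact" %in% names(series)) {
    series <- series[!series$artifact, ]
  }
  series <- series[!is.na(series$value_pct), ]
  series <- series[order(series$time_min), ]
  if (nrow(series) < 2 || t_start < min(series$time_min) ||
      t_end > max(series$time_min)) {
    abort_param("Window is outside the series support.")
  }
  tt <- sort(unique(c(t_start, t_end,
                      series$time_min[series$time_min > t_start &
                                        series$time_min < t_end])))
  vv <- stats::approx(series$time_min, series$value_pct, tt,
                      ties = "ordered")$y
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2) /
    (t_end - t_start)
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum test for two independent small samples with the U statistic
#' counted as the number of pairs `(a_i, b_j)` with `a_i > b_j` plus half a
#' count per tie, and the p-value taken from the exact permutation
#' distribution over all `choose(n1 + n2, n1)` group labelings of the
#' observed pooled values (so ties are handled exactly). For pooled sizes
#' above 20 a normal approximation with tie correction is used and noted in
#' the result.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param alternative `"two_sided"` (default), `"greater"` (a tends larger)
#'   or `"less"`.
#' @return A list of class `mw_test`: `U`, `p`, `alternative`, `method`,
#'   `n1`, `n2`.
#' @examples
#' mann_whitney_exact(1:5, 6:10)$p  # 2/252
#' @export
mann_whitney_exact <- function(a, b,
                               alternative = c("two_sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort_param("Empty group.")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)                      # midranks; U from rank-sum identity
  u_stat <- function(rank_sum) rank_sum - n1 * (n1 + 1) / 2
  U_obs <- u_stat(sum(r[seq_len(n1)]))

  if (n1 + n2 <= 20) {
    combos <- utils::combn(n1 + n2, n1)
    U_all <- u_stat(colSums(matrix(r[combos], nrow = n1)))
    n_tot <- ncol(combos)
    eps <- 1e-9
    p_ge <- sum(U_all >= U_obs - eps) / n_tot
    p_le <- sum(U_all <= U_obs + eps) / n_tot
    method <- "exact_enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    p_ge <- stats::pnorm(U_obs - 0.5, mu, sqrt(sig2), lower.tail = FALSE)
    p_le <- stats::pnorm(U_obs + 0.5, mu, sqrt(sig2))
    method <- "normal_approx"
  }
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two_sided = min(1, 2 * min(p_ge, p_le)))
  structure(list(U = U_obs, p = p, alternative = alternative,
                 method = method, n1 = n1, n2 = n2),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s): U = %.1f, p = %.4g (n = %d, %d)\n",
              x$method, x$alternative, x$U, x$p, x$n1, x$n2))
  invisible(x)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled standard deviation on `n1 + n2 - 2` degrees of freedom. Values
#' above 0.8 are conventionally considered large effects.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return Dimensionless effect size; `NA` with a warning if the pooled SD
#'   is zero.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort_param("Each group needs at least 2 values.")
  }
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) {
    warning("Zero pooled standard deviation; effect size undefined.",
            call. = FALSE)
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Group comparison of windowed hyperemia
#'
#' Reduces per-subject regional relative UfD series to time-normalized AUC
#' values over the analysis window, then compares the two groups with the
#' exact Mann-Whitney U test and Cohen's d, reporting per-group medians and
#' interquartile ranges (the box-plot quantities).
#'
#' @param series_tbl Long tibble as produced by [regional_series()] /
#'   [cohort_series()]: columns `subject`, `group`, `time_min`, `region`,
#'   `value_pct`, optionally `artifact`.
#' @param region Region to analyze.
#' @param window Length-2 numeric, AUC window in minutes (the hyperemia
#'   window 7-37 by default; 7-22 isolates the peak, 30-60 the late phase).
#' @param groups Optional length-2 character giving the group order
#'   (first vs second); defaults to the order of appearance.
#' @param alternative Passed to [mann_whitney_exact()].
#' @return An object of class `group_comparison`.
#' @export
group_compare <- function(series_tbl, region = "whole_slice",
                          window = c(7, 37), groups = NULL,
                          alternative = "two_sided") {
  stopifnot(is.data.frame(series_tbl))
  df <- dplyr::filter(series_tbl, .data$region == !!region)
  if (nrow(df) == 0) abort_param(sprintf("No data for region '%s'.", region))
  if (is.null(groups)) groups <- unique(df$group)
  if (length(groups) != 2) abort_param("Exactly two groups are required.")

  auc <- df |>
    dplyr::filter(.data$group %in% groups) |>
    dplyr::group_by(.data$group, .data$subject) |>
    dplyr::group_modify(~ tibble::tibble(
      auc_pct = normalized_auc(.x, window[1], window[2]))) |>
    dplyr::ungroup()
  if (any(table(auc$group) < 2)) {
    abort_param("Each group needs at least 2 subjects.")
  }

  x1 <- auc$auc_pct[auc$group == groups[1]]
  x2 <- auc$auc_pct[auc$group == groups[2]]
  test <- mann_whitney_exact(x1, x2, alternative = alternative)
  d <- cohens_d(x1, x2)

  summary_tbl <- auc |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_auc = stats::median(.data$auc_pct),
      q1 = stats::quantile(.data$auc_pct, 0.25),
      q3 = stats::quantile(.data$auc_pct, 0.75),
      mean_auc = mean(.data$auc_pct),
      sd_auc = stats::sd(.data$auc_pct),
      .groups = "drop"
    )

  structure(list(region = region, window = window, groups = groups,
                 auc = auc, test = test, cohens_d = d,
                 summary = summary_tbl),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s, window [%g, %g] min: %s vs %s\n",
              x$region, x$window[1], x$window[2], x$groups[1], x$groups[2]))
  print(x$summary)
  cat(sprintf("  U = %.1f, p = %.4g (%s), Cohen's d = %.2f\n",
              x$test$U, x$test$p, x$test$alternative, x$cohens_d))
  invisible(x)
}

#' @rdname group_compare
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$auc

#' @rdname group_compare
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    region = x$region,
    window_start = x$window[1], window_end = x$window[2],
    group1 = x$groups[1], group2 = x$groups[2],
    U = x$test$U, p_value = x$test$p, method = x$test$method,
    cohens_d = x$cohens_d,
    median_auc_1 = x$summary$median_auc[x$summary$group == x$groups[1]],
    median_auc_2 = x$summary$median_auc[x$summary$group == x$groups[2]]
  )
}

#' Combine per-subject series of a cohort
#'
#' Convenience wrapper streaming every subject of one or more cohorts into
#' the long regional series tibble used by [group_compare()] and
#' [autoregulation_cloud()].
#'
#' @param experiments List of `experiment_series` (possibly mixing groups).
#' @param regions A [region_set()].
#' @param spec An [svd_filter_spec()].
#' @param frames Frames per block.
#' @param baseline_window,noise_floor Passed to [regional_series()].
#' @return A list with `series` (long tibble) and `map` (per-subject MAP
#'   tibble with `subject`, `group`, `time_min`, `map_mmHg`).
#' @export
cohort_series <- function(experiments, regions,
                          spec = svd_filter_spec(),
                          frames = NULL,
                          baseline_window = c(-23, -13),
                          noise_floor = 0) {
  stopifnot(is.list(experiments))
  out <- purrr::map(experiments, function(series) {
    fr <- frames %||% series$config$frames_per_block
    pm <- power_map_series(series, spec = spec, frames = fr)
    list(series = regional_series(pm, regions,
                                  baseline_window = baseline_window,
                                  noise_floor = noise_floor),
         map = dplyr::mutate(series$map, subject = series$subject,
                             group = series$group, .before = 1))
  })
  list(series = purrr::map_dfr(out, "series"),
       map = purrr::map_dfr(out, "map"))
}
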