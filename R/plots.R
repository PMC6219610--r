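#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a parametric map
#'
#' Raster display of a power, relative-CBV or resistivity map. Power maps
#' are shown on a dB scale (display only; all computation is linear),
#' relative-CBV maps on a diverging percent scale centered at 0, and
#' resistivity maps on \[0, 1\].
#'
#' @param object A `parametric_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot parametric_map
#' @export
autoplot.parametric_map <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lateral_px, .data$depth_px))
  if (object$kind == "power") {
    df$db <- 10 * log10(pmax(df$value, max(df$value, na.rm = TRUE) * 1e-6))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$lateral_px, .data$depth_px)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$db)) +
      ggplot2::scale_fill_viridis_c(name = "power (dB)")
  } else if (object$kind == "relative_cbv") {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient2(name = "relative CBV (%)",
                                    low = "blue", mid = "white",
                                    high = "red", midpoint = 0)
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(name = "resistivity", limits = c(0, 1))
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral (px)", y = "depth (px)",
                  title = sprintf("%s map%s", object$kind,
                                  if (is.na(object$time_min)) "" else
                                    sprintf(" at t = %.1f min",
                                            object$time_min))) +
    ggplot2::theme_minimal()
}

#' Plot regional relative UfD time courses
#'
#' Group mean with a corrected-sample-SD ribbon per region, the standard
#' presentation of post-resuscitation hyperemia curves. Artifact-window
#' samples are drawn but marked.
#'
#' @param series_tbl Long series tibble (see [regional_series()]).
#' @param regions Regions to facet over.
#' @return A ggplot object.
#' @export
plot_region_series <- function(series_tbl,
                               regions = unique(series_tbl$region)) {
  df <- series_tbl |>
    dplyr::filter(.data$region %in% regions) |>
    dplyr::group_by(.data$group, .data$region, .data$time_min) |>
    dplyr::summarise(mean_pct = mean(.data$value_pct, na.rm = TRUE),
                     sd_pct = stats::sd(.data$value_pct),
                     artifact = any(.data$artifact), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$mean_pct,
                                   color = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_pct - .data$sd_pct,
                                      ymax = .data$mean_pct + .data$sd_pct),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$artifact),
                        shape = 4, size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "time after CPR (min)", y = "relative UfD (%)") +
    ggplot2::theme_minimal()
}

#' Plot a group AUC comparison
#'
#' Box plot of the per-subject time-normalized AUC values per group
#' (median, interquartile range and extremes) with the subject points
#' overlaid.
#'
#' @param object A `group_comparison` from [group_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$auc, ggplot2::aes(.data$group, .data$auc_pct,
                                           fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.5, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, height = 0) +
    ggplot2::labs(
      y = sprintf("normalized AUC %g-%g min (%%)", object$window[1],
                  object$window[2]),
      x = NULL,
      subtitle = sprintf("%s: p = %.3g, d = %.2f", object$region,
                         object$test$p, object$cohens_d)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a standardized CBV-MAP cloud with its principal axes
#'
#' @param cloud_tbl Cloud tibble of one group (see
#'   [autoregulation_cloud()]).
#' @param mode Standardization mode.
#' @return A ggplot object.
#' @export
plot_autoregulation <- function(cloud_tbl, mode = "pooled") {
  std <- standardize_pooled(cloud_tbl, mode = mode)
  p <- pca2(std)
  seg <- tibble::tibble(
    component = c("v1", "v2"),
    xend = sqrt(p$lambda) * p$v[1, ],
    yend = sqrt(p$lambda) * p$v[2, ]
  )
  ggplot2::ggplot(std, ggplot2::aes(.data$map_std, .data$cbv_std)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = 0, y = 0, xend = .data$xend,
                                       yend = .data$yend,
                                       color = .data$component),
                          arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm")),
                          linewidth = 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "standardized MAP", y = "standardized CBV") +
    ggplot2::theme_minimal()
}
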