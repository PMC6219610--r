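#' Build a CBV-versus-MAP point cloud
#'
#' Pairs the whole-slice relative UfD samples of each subject with the MAP
#' samples at the same block times over an analysis window, pooling subjects
#' of each group. The resulting cloud is the raw material of the PCA-based
#' autoregulation assessment: an intact autoregulation plateau shows CBV
#' nearly constant across a wide MAP range, while impairment shows large CBV
#' excursions decoupled from MAP.
#'
#' @param series_tbl Long regional series tibble (see [regional_series()]).
#' @param map_tbl MAP tibble with `subject`, `group`, `time_min`,
#'   `map_mmHg`.
#' @param window Length-2 numeric in minutes (default the post-resuscitation
#'   7-37 min window; use the full session for sham).
#' @param region Region whose series is used (whole slice by default).
#' @param drop_artifacts Exclude artifact-flagged samples.
#' @return A tibble with columns `group`, `subject`, `time_min`,
#'   `map_mmHg`, `cbv_pct`.
#' @export
autoregulation_cloud <- function(series_tbl, map_tbl, window = c(7, 37),
                                 region = "whole_slice",
                                 drop_artifacts = TRUE) {
  df <- dplyr::filter(series_tbl, .data$region == !!region,
                      .data$time_min >= window[1],
                      .data$time_min <= window[2])
  if (drop_artifacts && "artifact" %in% names(df)) {
    df <- dplyr::filter(df, !.data$artifact)
  }
  out <- df |>
    dplyr::inner_join(map_tbl,
                      by = c("subject", "group", "time_min")) |>
    dplyr::transmute(.data$group, .data$subject, .data$time_min,
                     .data$map_mmHg, cbv_pct = .data$value_pct) |>
    dplyr::filter(is.finite(.data$map_mmHg), is.finite(.data$cbv_pct))
  if (any(out$map_mmHg < 0 | out$map_mmHg > 300)) {
    abort_param("MAP samples outside physical bounds (0-300 mmHg).")
  }
  out
}

#' Standardize a CBV-MAP cloud
#'
#' Removes each variable's mean, then divides both centered variables by a
#' single pooled standard deviation computed over their concatenation (the
#' default), or by each variable's own standard deviation
#' (`mode = "per_variable"`, classic z-scores). Pooled standardization
#' preserves the relative spread of the two variables, so a plateau cloud
#' (wide MAP, flat CBV) keeps its near-horizontal principal axis; the two
#' modes coincide when the per-variable SDs are equal. The operation is
#' idempotent.
#'
#' @param cloud Data frame with columns `map_mmHg` and `cbv_pct` (at least
#'   3 rows, nonzero spread).
#' @param mode `"pooled"` or `"per_variable"`.
#' @return The cloud with columns `map_std`, `cbv_std` appended (means 0).
#' @export
standardize_pooled <- function(cloud, mode = c("pooled", "per_variable")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(cloud),
            all(c("map_mmHg", "cbv_pct") %in% names(cloud)))
  if (nrow(cloud) < 3) abort_param("Need at least 3 samples.")
  xc <- cloud$map_mmHg - mean(cloud$map_mmHg)
  yc <- cloud$cbv_pct - mean(cloud$cbv_pct)
  if (mode == "pooled") {
    s <- stats::sd(c(xc, yc))
    if (s == 0) abort_param("Zero spread in both variables.")
    sx <- sy <- s
  } else {
    sx <- stats::sd(xc); sy <- stats::sd(yc)
    if (sx == 0 || sy == 0) abort_param("Zero spread in a variable.")
  }
  dplyr::mutate(tibble::as_tibble(cloud),
                map_std = xc / sx, cbv_std = yc / sy)
}

#' 2-D principal component analysis of a standardized cloud
#'
#' Eigen-decomposition of the 2x2 sample covariance (n - 1 denominator) of
#' the standardized (MAP, CBV) samples. Returns unit eigenvectors `v1`,
#' `v2` (columns, coordinates ordered as (MAP, CBV)) with weights
#' `lambda1 >= lambda2 >= 0` summing to the total variance. Signs follow
#' the first-nonnegative-coordinate convention. `angle_deg` is the
#' orientation of `v1` relative to the MAP axis: near 0 for an
#' autoregulation plateau, near 90 when CBV varies independently of MAP.
#'
#' @param cloud A standardized cloud from [standardize_pooled()] (columns
#'   `map_std`, `cbv_std`), or any data frame with those columns.
#' @return An object of class `ufd_pca`.
#' @export
pca2 <- function(cloud) {
  stopifnot(is.data.frame(cloud),
            all(c("map_std", "cbv_std") %in% names(cloud)))
  if (nrow(cloud) < 3) abort_param("Need at least 3 samples.")
  M <- cbind(map = cloud$map_std, cbv = cloud$cbv_std)
  S <- stats::cov(M)
  if (all(abs(S) < .Machine$double.eps)) {
    abort_param("Degenerate cloud: zero covariance.")
  }
  eg <- eigen(S, symmetric = TRUE)
  V <- eg$vectors
  for (j in 1:2) {
    lead <- which(abs(V[, j]) > 1e-12)[1]
    if (V[lead, j] < 0) V[, j] <- -V[, j]
  }
  lambda <- pmax(eg$values, 0)
  structure(
    list(v = V, lambda = lambda, n = nrow(cloud),
         angle_deg = atan2(V[2, 1], V[1, 1]) * 180 / pi),
    class = "ufd_pca"
  )
}

#' @export
print.ufd_pca <- function(x, ...) {
  cat(sprintf(
    "<ufd_pca> v1 = (%.2f, %.2f), v2 = (%.2f, %.2f); lambda = (%.3g, %.3g), ratio %.3g, angle %.1f deg\n",
    x$v[1, 1], x$v[2, 1], x$v[1, 2], x$v[2, 2],
    x$lambda[1], x$lambda[2], weight_ratio(x), x$angle_deg))
  invisible(x)
}

#' @rdname pca2
#' @param x A `ufd_pca`.
#' @param ... Unused.
#' @method tidy ufd_pca
#' @export
tidy.ufd_pca <- function(x, ...) {
  tibble::tibble(
    component = c("v1", "v2"),
    map = x$v[1, ], cbv = x$v[2, ],
    lambda = x$lambda
  )
}

#' @rdname pca2
#' @method glance ufd_pca
#' @export
glance.ufd_pca <- function(x, ...) {
  tibble::tibble(lambda1 = x$lambda[1], lambda2 = x$lambda[2],
                 weight_ratio = weight_ratio(x),
                 angle_deg = x$angle_deg, n = x$n)
}

#' Principal-weight ratio
#'
#' The anisotropy `lambda1 / lambda2` of the standardized cloud: large when
#' the cloud concentrates along one axis (plateau or strict linear
#' coupling), near 1 when variance is spread isotropically (decoupled CBV
#' and MAP). Returns `Inf` when `lambda2` is zero.
#'
#' @param x A `ufd_pca`, or a numeric vector of two weights.
#' @return Dimensionless ratio.
#' @examples
#' weight_ratio(c(1.20, 0.040))  # 30
#' @export
weight_ratio <- function(x) {
  lam <- if (inherits(x, "ufd_pca")) x$lambda else as.numeric(x)
  stopifnot(length(lam) == 2)
  if (lam[2] == 0) return(Inf)
  lam[1] / lam[2]
}

#' Per-group autoregulation assessment
#'
#' Standardizes each group's CBV-MAP cloud, runs the 2-D PCA and classifies
#' the autoregulation regime:
#'
#' * `plateau` - principal axis nearly horizontal (|angle| below
#'   `angle_threshold`) with strong anisotropy: CBV held constant across a
#'   wide MAP range (intact autoregulation).
#' * `linear_steep` - CBV strongly correlated with MAP but along a steep
#'   axis: autoregulation lost, passive pressure-driven CBV.
#' * `impaired` - CBV excursions decoupled from MAP (absolute Pearson
#'   correlation below `cor_threshold`): no regulation and no passive
#'   coupling either.
#'
#' The unit-dependent weight ratio alone cannot separate the last two
#' regimes under pooled standardization, which is why the correlation
#' enters the rule; all three diagnostics are reported.
#'
#' @param cloud_tbl A cloud tibble (see [autoregulation_cloud()]) holding
#'   one or more `group`s.
#' @param mode Standardization mode (see [standardize_pooled()]).
#' @param angle_threshold Degrees; maximum |angle| of a plateau axis.
#' @param ratio_threshold Minimum weight ratio of a plateau.
#' @param cor_threshold Minimum |correlation| for linear coupling.
#' @return A tibble with one row per group: `group`, `n`, `lambda1`,
#'   `lambda2`, `weight_ratio`, `angle_deg`, `correlation`, `label`; the
#'   fitted `ufd_pca` objects are attached as attribute `"pca"`.
#' @export
autoregulation_report <- function(cloud_tbl, mode = "pooled",
                                  angle_threshold = 15,
                                  ratio_threshold = 5,
                                  cor_threshold = 0.5) {
  stopifnot(is.data.frame(cloud_tbl), "group" %in% names(cloud_tbl))
  groups <- unique(cloud_tbl$group)
  fits <- purrr::map(stats::setNames(nm = groups), function(g) {
    cl <- dplyr::filter(cloud_tbl, .data$group == g)
    std <- standardize_pooled(cl, mode = mode)
    list(pca = pca2(std), cor = stats::cor(cl$map_mmHg, cl$cbv_pct),
         n = nrow(cl))
  })
  out <- purrr::map_dfr(groups, function(g) {
    f <- fits[[g]]
    ratio <- weight_ratio(f$pca)
    label <- if (abs(f$pca$angle_deg) < angle_threshold &&
                 ratio > ratio_threshold) {
      "plateau"
    } else if (abs(f$cor) < cor_threshold) {
      "impaired"
    } else {
      "linear_steep"
    }
    tibble::tibble(group = g, n = f$n,
                   lambda1 = f$pca$lambda[1], lambda2 = f$pca$lambda[2],
                   weight_ratio = ratio, angle_deg = f$pca$angle_deg,
                   correlation = f$cor, label = label)
  })
  attr(out, "pca") <- purrr::map(fits, "pca")
  out
}
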