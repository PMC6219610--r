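rand_cloud <- function(n, sx = 2, sy = 1, rho = 0, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  tibble::tibble(map_mmHg = 80 + sx * x, cbv_pct = 10 + sy * y)
}

test_that("standardization centers, scales and is idempotent", {
  cl <- rand_cloud(200, sx = 3, sy = 1, seed = 2)
  std <- standardize_pooled(cl)
  expect_lt(abs(mean(std$map_std)), 1e-12)
  expect_lt(abs(mean(std$cbv_std)), 1e-12)
  expect_equal(stats::sd(c(std$map_std, std$cbv_std)), 1)
  # pooled scaling preserves the relative spread of the two variables
  expect_equal(stats::sd(std$map_std) / stats::sd(std$cbv_std),
               stats::sd(cl$map_mmHg) / stats::sd(cl$cbv_pct))
  # idempotence
  std2 <- standardize_pooled(
    dplyr::transmute(std, map_mmHg = .data$map_std,
                     cbv_pct = .data$cbv_std))
  expect_equal(std2$map_std, std$map_std)
  # equal per-variable spreads: pooled coincides with z-scores
  cl_eq <- rand_cloud(500, sx = 1.5, sy = 1.5, seed = 3)
  a <- standardize_pooled(cl_eq, mode = "pooled")
  b <- standardize_pooled(cl_eq, mode = "per_variable")
  expect_equal(a$map_std, b$map_std, tolerance = 0.05)
  expect_error(standardize_pooled(cl[1:2, ]), class = "ufd_parameter_error")
  expect_error(standardize_pooled(
    tibble::tibble(map_mmHg = rep(1, 5), cbv_pct = rep(2, 5))),
    class = "ufd_parameter_error")
})

test_that("pca2 recovers axis-aligned and rotated structure", {
  # points on the MAP axis
  cl <- tibble::tibble(map_std = c(-2, -1, 0, 1, 2), cbv_std = 0)
  p <- pca2(cl)
  expect_equal(p$v[, 1], c(1, 0))
  expect_equal(p$lambda[2], 0)
  expect_equal(p$angle_deg, 0)
  # algebraic identities on random clouds
  for (s in 1:5) {
    std <- standardize_pooled(rand_cloud(60, sx = 2, sy = 1, rho = 0.4,
                                         seed = s))
    p <- pca2(std)
    expect_equal(crossprod(p$v), diag(2), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_gte(p$lambda[1], p$lambda[2])
    S <- stats::cov(cbind(std$map_std, std$cbv_std))
    expect_equal(sum(p$lambda), sum(diag(S)))
    # sign convention: leading nonzero coordinate is nonnegative
    expect_gte(p$v[1, 1], 0)
  }
  # rotation equivariance: rotating the cloud rotates the vectors
  std <- standardize_pooled(rand_cloud(80, sx = 3, sy = 1, seed = 9))
  p0 <- pca2(std)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  M <- as.matrix(std[, c("map_std", "cbv_std")]) %*% t(R)
  p1 <- pca2(tibble::tibble(map_std = M[, 1], cbv_std = M[, 2]))
  expect_equal(p1$lambda, p0$lambda, tolerance = 1e-12)
  v1_rot <- R %*% p0$v[, 1]
  expect_equal(abs(sum(v1_rot * p1$v[, 1])), 1, tolerance = 1e-12)
  # a 90-degree rotation swaps the component roles
  M90 <- as.matrix(std[, c("map_std", "cbv_std")]) %*%
    t(matrix(c(0, 1, -1, 0), 2))
  p90 <- pca2(tibble::tibble(map_std = M90[, 1], cbv_std = M90[, 2]))
  expect_equal(abs(p90$v[2, 1]), abs(p0$v[1, 1]), tolerance = 1e-12)
  expect_error(pca2(tibble::tibble(map_std = rep(0, 5), cbv_std = 0)),
               class = "ufd_parameter_error")
})

test_that("an isotropic cloud has weight ratio near one at large n", {
  std <- standardize_pooled(rand_cloud(5000, sx = 1, sy = 1, seed = 4))
  expect_lt(weight_ratio(pca2(std)), 1.2)
})

test_that("known principal axes are recovered from sampled clouds", {
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  set.seed(6)
  Z <- cbind(stats::rnorm(200, sd = 3), stats::rnorm(200, sd = 1)) %*% t(R)
  std <- standardize_pooled(tibble::tibble(map_mmHg = Z[, 1],
                                           cbv_pct = Z[, 2]))
  p <- pca2(std)
  expect_lt(abs(p$angle_deg - 25), 5)
  expect_lt(abs(weight_ratio(p) - 9) / 9, 0.35)
  # standardized total variance is fixed, split 9:1
  expect_equal(p$lambda[1] / sum(p$lambda), 0.9, tolerance = 0.05)
})

test_that("the reported principal weights reproduce their ratios", {
  # (lambda1, lambda2) pairs of the three study arms
  expect_equal(weight_ratio(c(1.20, 0.040)), 30)
  expect_equal(round(weight_ratio(c(1.79, 0.18)), 2), 9.94)
  expect_equal(round(weight_ratio(c(0.66, 0.34)), 2), 1.94)
  expect_equal(weight_ratio(c(1, 0)), Inf)
  # the corresponding printed vector pairs are orthonormal within rounding
  vecs <- list(sham = cbind(c(0.99, 0.14), c(-0.14, 0.99)),
               tlv = cbind(c(0.73, 0.68), c(-0.68, 0.73)),
               control = cbind(c(0.34, 0.94), c(0.94, -0.34)))
  for (V in vecs) {
    expect_equal(sqrt(colSums(V^2)), c(1, 1), tolerance = 0.01)
    expect_lt(abs(sum(V[, 1] * V[, 2])), 0.02)
  }
})

test_that("autoregulation regimes are classified from template cohorts", {
  cfg <- tiny_config()
  reg <- region_set(c(16, 16))
  sham <- make_experiment(hemodynamic_template("sham"), cfg, 5, seed = 71,
                          regions = reg)
  ch <- gt_cohort(n = 5, seed = 72)
  sham_series <- purrr::map_dfr(sham, ground_truth_series,
                                cbv_noise_sd = 2.5, seed = 70)
  sham_map <- purrr::map_dfr(sham, function(s) {
    dplyr::mutate(s$map, subject = s$subject, group = s$group, .before = 1)
  })
  clouds <- dplyr::bind_rows(
    autoregulation_cloud(sham_series, sham_map, window = c(0, 10)),
    autoregulation_cloud(ch$series, ch$map, window = c(7, 37)))
  rep <- autoregulation_report(clouds)
  lab <- stats::setNames(rep$label, rep$group)
  expect_equal(lab[["sham"]], "plateau")
  expect_equal(lab[["control"]], "impaired")
  expect_equal(lab[["tlv"]], "linear_steep")
  # plateau diagnostics as designed: near-horizontal axis, high anisotropy
  expect_lt(abs(rep$angle_deg[rep$group == "sham"]), 15)
  expect_gt(rep$weight_ratio[rep$group == "sham"], 5)
  # artifact-window samples are excluded from clouds
  expect_false(any(ch$series$time_min[ch$series$artifact] %in%
                     clouds$time_min[clouds$group == "control"]))
})

test_that("clouds reject unphysical MAP values", {
  ser <- tibble::tibble(subject = 1, group = "g", time_min = 1:5,
                        region = "whole_slice", value_pct = 1:5,
                        artifact = FALSE)
  mp <- tibble::tibble(subject = 1, group = "g", time_min = 1:5,
                       map_mmHg = c(70, 80, 90, 100, 500))
  expect_error(autoregulation_cloud(ser, mp, window = c(1, 5)),
               class = "ufd_parameter_error")
})
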