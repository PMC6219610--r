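# Shared fixtures: everything is generated in code at test time.

tiny_config <- function(nz = 16, nx = 16, nt = 50, ...) {
  acquisition_config(grid_shape = c(nz, nx), frames_per_block = nt, ...)
}

uniform_regions <- function(nz, nx, name = "vessel") {
  structure(stats::setNames(list(matrix(TRUE, nz, nx)), name),
            class = "region_set", grid_shape = c(nz, nx))
}

# A field holding exactly the given blood scatterers and no tissue/noise.
bare_blood_field <- function(config, blood,
                             heart_rate = 4, seed = 1) {
  nz <- config$grid_shape[1]; nx <- config$grid_shape[2]
  fld <- scatterer_field(config, regions = uniform_regions(nz, nx),
                         blood_density = 0, tissue_to_blood_db = -300,
                         noise_to_blood_db = -300, heart_rate = heart_rate,
                         seed = seed)
  fld$tissue_img[] <- 0 + 0i
  fld$noise_sd <- 0
  fld$cardiac_phase <- 0
  fld$blood <- blood
  fld
}

one_scatterer <- function(pixel, v, phase0 = 0, sign = 1) {
  tibble::tibble(region = "vessel", pixel = as.integer(pixel), sign = sign,
                 jitter = 1, phase0 = phase0,
                 v_systolic = v, v_diastolic = v)
}

wrap_phase <- function(x) ((x + pi) %% (2 * pi)) - pi

# Independent exact Mann-Whitney oracle: U by direct pair counting, p by
# enumerating every labeling of the pooled sample (no rank-sum shortcut).
mw_oracle <- function(a, b, alternative = "two_sided") {
  u_pairs <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  U <- u_pairs(a, b)
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a))
  U_all <- apply(idx, 2, function(k) u_pairs(pool[k], pool[-k]))
  eps <- 1e-9
  p_ge <- mean(U_all >= U - eps)
  p_le <- mean(U_all <= U + eps)
  p <- switch(alternative,
              greater = p_ge, less = p_le,
              two_sided = min(1, 2 * min(p_ge, p_le)))
  list(U = U, p = p)
}

# Ground-truth-level two-arm cohort series (no IQ synthesis).
gt_cohort <- function(n = 5, seed = 1, noise_sd = 3) {
  cfg <- tiny_config()
  reg <- region_set(c(16, 16))
  exc <- make_experiment(hemodynamic_template("control"), cfg, n,
                         seed = seed, regions = reg)
  ext <- make_experiment(hemodynamic_template("tlv"), cfg, n,
                         seed = seed + 5000, regions = reg)
  list(
    series = dplyr::bind_rows(
      purrr::map_dfr(exc, ground_truth_series, cbv_noise_sd = noise_sd,
                     seed = seed),
      purrr::map_dfr(ext, ground_truth_series, cbv_noise_sd = noise_sd,
                     seed = seed + 1)),
    map = dplyr::bind_rows(
      purrr::map_dfr(c(exc, ext), function(s) {
        dplyr::mutate(s$map, subject = s$subject, group = s$group,
                      .before = 1)
      }))
  )
}
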