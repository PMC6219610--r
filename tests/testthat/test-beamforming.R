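small_geom <- function() array_geometry(n_elements = 32, pitch = 3e-4,
                                        fs = 32e6)
small_grid <- list(z = seq(2e-3, 6e-3, by = 1e-4),
                   x = seq(-2e-3, 2e-3, by = 1e-4))

test_that("plane-wave channel delays follow the analytic two-way formula", {
  cfg <- acquisition_config()
  geom <- small_geom()
  z0 <- 4e-3
  rec <- simulate_rf_plane_wave(data.frame(x = 0, z = z0), geom, cfg,
                                angle = 0)
  # central element: envelope peak at 2 z / c plus half the burst
  e_mid <- which.min(abs(geom$positions))
  env <- stats::filter(abs(rec$data[, e_mid]), rep(1, 9) / 9, sides = 2)
  t_peak <- (which.max(env) - 1) / geom$fs
  t_theory <- 2 * z0 / cfg$sound_speed + rec$burst_s / 2
  expect_lt(abs(t_peak - t_theory), 1 / cfg$center_frequency)

  # tilted transmit adds x sin(theta) / c to the one-way path
  x0 <- 2e-3
  rec0 <- simulate_rf_plane_wave(data.frame(x = x0, z = z0), geom, cfg,
                                 angle = 0)
  rec3 <- simulate_rf_plane_wave(data.frame(x = x0, z = z0), geom, cfg,
                                 angle = 3)
  lagdiff <- function(rec) {
    e <- which.min(abs(geom$positions - x0))
    (which.max(abs(rec$data[, e])) - 1) / geom$fs
  }
  shift <- lagdiff(rec3) - lagdiff(rec0)
  th <- 3 * pi / 180
  # peak positions quantize to the channel sampling grid
  expect_lt(abs(shift - (z0 * (cos(th) - 1) + x0 * sin(th)) /
                  cfg$sound_speed), 1 / geom$fs)
})

test_that("scatterers outside the aperture are excluded with a warning", {
  cfg <- acquisition_config()
  geom <- small_geom()
  expect_warning(
    rec <- simulate_rf_plane_wave(data.frame(x = c(0, 0.05), z = c(4e-3, 4e-3)),
                                  geom, cfg, angle = 0),
    "outside")
  expect_silent(simulate_rf_plane_wave(data.frame(x = 0, z = 4e-3)[0, ],
                                       geom, cfg, angle = 0))
})

test_that("delay-and-sum localizes point targets within one pixel", {
  cfg <- acquisition_config()
  geom <- small_geom()
  targets <- data.frame(x = c(0, -1.2e-3), z = c(3e-3, 5e-3))
  for (k in seq_len(nrow(targets))) {
    for (ang in c(0, 3)) {
      rec <- simulate_rf_plane_wave(targets[k, ], geom, cfg, angle = ang)
      img <- das_beamform(rec, small_grid$z, small_grid$x)
      peak <- which(Mod(img$data) == max(Mod(img$data)), arr.ind = TRUE)
      expect_lte(abs(small_grid$z[peak[1]] - targets$z[k]), 1.5e-4)
      expect_lte(abs(small_grid$x[peak[2]] - targets$x[k]), 1.5e-4)
    }
  }
})

test_that("two well-separated scatterers give two local maxima", {
  cfg <- acquisition_config()
  geom <- small_geom()
  sc <- data.frame(x = c(-1.5e-3, 1.5e-3), z = c(3e-3, 5e-3))
  rec <- simulate_rf_plane_wave(sc, geom, cfg, angle = 0)
  img <- Mod(das_beamform(rec, small_grid$z, small_grid$x)$data)
  for (k in 1:2) {
    iz <- which.min(abs(small_grid$z - sc$z[k]))
    ix <- which.min(abs(small_grid$x - sc$x[k]))
    nb <- img[pmax(1, iz - 2):pmin(nrow(img), iz + 2),
              pmax(1, ix - 2):pmin(ncol(img), ix + 2)]
    expect_gt(max(nb), 0.5 * max(img))
  }
})

test_that("beamforming is linear and zero data give a zero image", {
  cfg <- acquisition_config()
  geom <- small_geom()
  recA <- simulate_rf_plane_wave(data.frame(x = 0, z = 3e-3), geom, cfg, 0,
                                 max_depth = 6e-3)
  recB <- simulate_rf_plane_wave(data.frame(x = 1e-3, z = 5e-3), geom, cfg, 0,
                                 max_depth = 6e-3)
  recS <- recA; recS$data <- recA$data + recB$data
  bf <- function(r) das_beamform(r, small_grid$z, small_grid$x)$data
  expect_equal(bf(recS), bf(recA) + bf(recB), tolerance = 1e-10)
  rec0 <- recA; rec0$data[] <- 0
  expect_equal(bf(rec0), matrix(0 + 0i, length(small_grid$z),
                                length(small_grid$x)))
})

test_that("coherent compounding is the complex mean with its identities", {
  set.seed(1)
  im <- matrix(complex(real = rnorm(100), imaginary = rnorm(100)), 10, 10)
  mk <- function(data, ang) structure(list(data = data, angle = ang,
                                           grid_z = 1:10, grid_x = 1:10),
                                      class = "angled_image")
  # compounding four copies returns the image
  expect_equal(coherent_compound(lapply(1:4, function(a) mk(im, a))),
               im, ignore_attr = TRUE)
  # opposite phases cancel
  expect_equal(coherent_compound(list(mk(im, 0), mk(-im, 1))),
               matrix(0 + 0i, 10, 10), ignore_attr = TRUE)
  # triangle inequality: |mean| <= mean of moduli
  im2 <- matrix(complex(real = rnorm(100), imaginary = rnorm(100)), 10, 10)
  comp <- coherent_compound(list(mk(im, 0), mk(im2, 1)))
  expect_true(all(Mod(comp) <= (Mod(im) + Mod(im2)) / 2 + 1e-12))
  # mismatched grids error
  expect_error(coherent_compound(list(mk(im, 0), mk(im[1:5, ], 1))),
               class = "ufd_parameter_error")
})

test_that("compounding reduces point-target sidelobes", {
  cfg <- acquisition_config()
  geom <- small_geom()
  target <- data.frame(x = 0, z = 4e-3)
  imgs <- lapply(cfg$tilt_angles, function(a) {
    das_beamform(simulate_rf_plane_wave(target, geom, cfg, angle = a),
                 small_grid$z, small_grid$x)
  })
  comp <- Mod(coherent_compound(imgs))
  single <- Mod(imgs[[1]]$data)
  # relative level of the strongest off-axis response does not get worse
  off_comp <- max(comp[abs(seq_along(small_grid$z) -
                             which.min(abs(small_grid$z - 4e-3))) > 3, ]) /
    max(comp)
  off_single <- max(single[abs(seq_along(small_grid$z) -
                                 which.min(abs(small_grid$z - 4e-3))) > 3, ]) /
    max(single)
  expect_lte(off_comp, off_single + 1e-6)
})
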