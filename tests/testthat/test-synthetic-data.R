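test_that("pulsatile waveform attains its extrema and period", {
  hr <- 4; vs <- 0.10; vd <- 0.04
  t <- seq(0, 1 / hr, length.out = 2001)
  v <- pulsatile_velocity(t, hr, vs, vd)
  expect_equal(max(v), vs)
  expect_equal(min(v), vd, tolerance = 1e-6)
  # systolic peak sits mid-upstroke
  expect_equal(pulsatile_velocity(0.45 / 2 / hr, hr, vs, vd), vs)
  # periodicity
  expect_equal(pulsatile_velocity(t, hr, vs, vd),
               pulsatile_velocity(t + 3 / hr, hr, vs, vd))
  # degenerate pulse
  expect_equal(pulsatile_velocity(t, hr, 0.05, 0.05), rep(0.05, length(t)))
  expect_error(pulsatile_velocity(0, hr, 0.02, 0.04),
               class = "ufd_parameter_error")
  expect_error(pulsatile_velocity(0, -1, 0.1, 0.04),
               class = "ufd_parameter_error")
})

test_that("IQ synthesis is deterministic and static fields are rank one", {
  cfg <- tiny_config(nt = 40)
  fld <- scatterer_field(cfg, blood_density = 0, noise_to_blood_db = -300,
                         tissue_motion_amplitude = 0, seed = 2)
  b1 <- simulate_iq_block(fld, cfg, seed = 3)
  b2 <- simulate_iq_block(fld, cfg, seed = 3)
  expect_identical(b1$data, b2$data)
  # static tissue: all frames identical, Casorati rank 1
  expect_equal(b1$data[, , 1], b1$data[, , 40])
  sv <- svd(to_casorati(b1))$d
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("a constant-velocity scatterer advances phase by 4 pi f0 v dt / c", {
  cfg <- tiny_config(nz = 8, nx = 8, nt = 30)
  v <- 0.03
  fld <- bare_blood_field(cfg, one_scatterer(5, v, phase0 = 0.3))
  blk <- simulate_iq_block(fld, cfg, seed = 9)
  px <- blk$data[5, 1, ]
  inc <- wrap_phase(diff(Arg(px)))
  theory <- wrap_phase(4 * pi * cfg$center_frequency * v /
                         (cfg$sound_speed * compound_frame_rate(cfg)))
  expect_equal(inc, rep(theory, length(inc)), tolerance = 1e-8)
})

test_that("Doppler frequency of constant-velocity pixels peaks at 2 f0 v / c", {
  cfg <- tiny_config(nz = 8, nx = 8, nt = 200)
  fs <- compound_frame_rate(cfg)
  for (v in c(0.02, 0.06, -0.09)) {
    fld <- bare_blood_field(cfg, one_scatterer(11, abs(v),
                                               sign = sign(v)))
    blk <- simulate_iq_block(fld, cfg, seed = 5)
    px <- matrix(blk$data, 64, 200)[11, ]
    spec <- Mod(stats::fft(px))^2
    fr <- (0:199) * fs / 200
    fr[fr > fs / 2] <- fr[fr > fs / 2] - fs
    f_peak <- fr[which.max(spec)]
    f_theory <- 2 * cfg$center_frequency * v / cfg$sound_speed
    expect_lt(abs(f_peak - f_theory), fs / 200)  # within one bin
  }
})

test_that("tissue energy dominates blood energy by the configured margin", {
  cfg <- tiny_config(nt = 60)
  fld <- scatterer_field(cfg, blood_density = 3, tissue_to_blood_db = 30,
                         seed = 7)
  fldT <- fld; fldT$blood <- fld$blood[0, ]; fldT$noise_sd <- 0
  fldB <- fld; fldB$tissue_img[] <- 0; fldB$noise_sd <- 0
  eT <- sum(Mod(simulate_iq_block(fldT, cfg, seed = 1)$data)^2)
  eB <- sum(Mod(simulate_iq_block(fldB, cfg, seed = 1)$data)^2)
  expect_gt(eT / eB, 10^(20 / 10))  # at least 20 dB of the configured 30
})

test_that("speeds beyond half the aliasing-free span flag the block", {
  cfg <- tiny_config(nz = 8, nx = 8, nt = 20)
  fld <- bare_blood_field(cfg, one_scatterer(3, 0.2))  # > 0.1203 m/s
  expect_warning(blk <- simulate_iq_block(fld, cfg, seed = 1), "alias")
  expect_true(blk$aliased)
})

test_that("templates honor their protocol invariants", {
  ctl <- hemodynamic_template("control")
  tlv <- hemodynamic_template("tlv")
  sham <- hemodynamic_template("sham")
  regions <- c("whole_slice", "cortex", "hippocampus", "thalamus")
  # baseline anchored at 0%
  for (tpl in list(ctl, tlv)) {
    for (r in regions) {
      expect_equal(template_cbv(tpl, r, seq(-23, -13, by = 0.5)),
                   rep(0, 21))
    }
  }
  expect_equal(template_cbv(sham, "whole_slice", seq(0, 4, by = 0.5)),
               rep(0, 9), tolerance = 1e-6)
  # control peaks: +150% whole slice, +210% hippocampus, near t = 10
  tt <- seq(-23, 67, by = 0.25)
  ws <- template_cbv(ctl, "whole_slice", tt)
  expect_equal(max(ws), 150)
  expect_equal(tt[which.max(ws)], 10)
  expect_equal(max(template_cbv(ctl, "hippocampus", tt)), 210)
  expect_equal(max(template_cbv(ctl, "thalamus", tt)), 126.6)
  # mitigation: tlv pointwise at or below control during 7-37 min
  win <- seq(7, 37, by = 0.25)
  for (r in regions) {
    expect_true(all(template_cbv(tlv, r, win) <=
                      template_cbv(ctl, r, win) + 1e-9))
  }
  # MAP inside the physiological 60-90 mmHg band after resuscitation
  for (tpl in list(ctl, tlv)) {
    m <- template_map(tpl, seq(2, 67, by = 0.5))
    expect_true(all(m >= 60 & m <= 90))
  }
  # whole-slice AUC 7-37 near the designed group levels
  auc <- function(tpl) {
    normalized_auc(tibble::tibble(time_min = win,
                                  value_pct = template_cbv(tpl, "whole_slice",
                                                           win)), 7, 37)
  }
  expect_gt(auc(ctl), 75); expect_lt(auc(ctl), 95)
  expect_gt(auc(tlv), 15); expect_lt(auc(tlv), 35)
})

test_that("experiments sample the protocol and scale densities with CBV", {
  cfg <- tiny_config()
  reg <- region_set(c(16, 16))
  # sham: 10-minute session, one image every 6 s -> about 100 blocks
  sham <- make_experiment(hemodynamic_template("sham"), cfg, 1, seed = 3,
                          regions = reg)[[1]]
  expect_equal(length(sham$times_min), 101)
  expect_equal(diff(sham$times_min[1:2]) * 60, 6)

  ctl <- make_experiment(hemodynamic_template("control"), cfg, 2, seed = 4,
                         regions = reg, block_interval_s = 60)[[1]]
  # baseline blocks: density multiplier 1, relative CBV 0
  base_idx <- ctl$times_min <= -13
  expect_equal(ctl$multipliers$cortex[base_idx],
               rep(1, sum(base_idx)))
  # whole-slice multiplier peaks near 2.5x baseline (x subject factor)
  g <- ctl$ground_truth$global_factor
  ws_mult <- 1 + ctl$ground_truth$curves$whole_slice / 100
  expect_equal(max(ws_mult), 1 + 1.5 * g, tolerance = 1e-8)
  # artifact window flagged
  expect_true(all(ctl$artifact[ctl$times_min >= 23 & ctl$times_min <= 26]))
  expect_false(any(ctl$artifact[ctl$times_min < 23]))
  # determinism of the whole cohort
  ctl2 <- make_experiment(hemodynamic_template("control"), cfg, 2, seed = 4,
                          regions = reg, block_interval_s = 60)[[1]]
  expect_identical(ctl$ground_truth, ctl2$ground_truth)
  expect_identical(series_block(ctl, 5)$data, series_block(ctl2, 5)$data)
})

test_that("recovered regional series reproduces the template curves", {
  cfg <- tiny_config(nt = 100)
  reg <- region_set(c(16, 16))
  ser <- make_experiment(hemodynamic_template("control"), cfg, 1, seed = 11,
                         regions = reg, block_interval_s = 120)[[1]]
  pm <- power_map_series(ser)
  rs <- regional_series(pm, reg)
  gt <- ground_truth_series(ser)
  cmp <- dplyr::inner_join(rs, gt,
                           by = c("subject", "group", "time_min", "region"),
                           suffix = c("", "_gt"))
  # template fidelity: recovered curve tracks ground truth
  expect_gt(stats::cor(cmp$value_pct, cmp$value_pct_gt), 0.97)
  expect_lt(stats::median(abs(cmp$value_pct - cmp$value_pct_gt)), 12)
})
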