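test_that("generation is deterministic: identical seed gives bit-identical data", {
  cfg <- sim_config(seed = 5, fs_hz = 1000,
                    duration_s = c(vehicle = 5, drug = 10, antagonist = 5))
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(sim_config(seed = 6, fs_hz = 1000,
                                      duration_s = cfg$duration_s))
  expect_false(identical(r1$data, r3$data))
})

test_that("epoch table is ordered, half-open and consistent with durations", {
  cfg <- sim_config(seed = 1, fs_hz = 1000,
                    duration_s = c(vehicle = 5, drug = 10, antagonist = 5))
  rec <- simulate_recording(cfg)
  ep <- rec$epochs
  expect_equal(ep$label, c("vehicle", "kainate", "kainate_bicuculline"))
  expect_equal(ep$t_start_s, c(0, 5, 15))
  expect_equal(ep$t_end_s, c(5, 15, 20))
  expect_equal(ncol(rec$data), 20 * 1000)
  expect_false(anyNA(rec$data))
  # epoch_samples respects the half-open convention
  s <- epoch_samples(rec, "vehicle")
  expect_equal(range(s), c(1, 5000))
})

test_that("vehicle epoch is noise-only and the reference electrode stays silent", {
  cfg <- sim_config(seed = 2, fs_hz = 1000,
                    duration_s = c(vehicle = 10, drug = 20, antagonist = 5),
                    onset = list(a = 6, b = 0.05), noise_sd_uv = 4)
  rec <- simulate_recording(cfg)
  iv <- epoch_samples(rec, "vehicle")
  id <- epoch_samples(rec, "kainate", last_s = 5)
  ref <- rec$layout$electrode_id[rec$layout$is_reference] + 1
  ca1 <- recording_electrodes(rec$layout, "CA1")[1] + 1
  # vehicle variance ~ noise variance for every channel
  expect_lt(max(abs(apply(rec$data[, iv], 1, sd) - 4)), 0.5)
  # drug epoch adds oscillatory power on recording channels, not the reference
  expect_gt(sd(rec$data[ca1, id]), 1.5 * sd(rec$data[ca1, iv]))
  expect_lt(abs(sd(rec$data[ref, id]) - 4), 0.5)
})

test_that("narrowband source peak frequency and bandwidth are recovered spectrally", {
  # narrow-band config: with realistically broad peaks (FWHM ~ 30 Hz) the argmax
  # of a finite-variance PSD estimate jitters by several Hz, so the +-1 Hz
  # recovery check uses B = 6 Hz
  set.seed(31)
  fs <- 1000
  x <- narrowband_noise(240 * fs, fs, peak_hz = 30, bandwidth_hz = 6, sd = 5)
  lfp <- fake_lfp(matrix(x, nrow = 1), fs, layout = make_layout())
  ps <- epoch_psd(lfp, channel = 0, samples = seq_along(x), window_s = 4)
  pk <- peak_and_q(ps)
  expect_lt(abs(pk$f0 - 30), 1)
  expect_lt(abs(pk$B - 6) / 6, 0.2)
})

test_that("measured within-region coherence matches the analytic shared-source oracle", {
  # plateau reached quickly so the condition window sees envelope ~ 1
  cfg <- sim_config(seed = 9, fs_hz = 2000,
                    duration_s = c(vehicle = 20, drug = 150, antagonist = 20),
                    onset = list(a = 8, b = 0.1))
  rec <- simulate_recording(cfg)
  lfp <- downsample(lowpass_lfp(rec), 1000)
  ca1 <- recording_electrodes(lfp$layout, "CA1")[1:2]
  id <- epoch_samples(lfp, "kainate", last_s = 100)
  cs <- multitaper_coherence(lfp$data[ca1[1] + 1, id],
                             lfp$data[ca1[2] + 1, id], 1000)
  expect_lt(abs(band_coherence(cs) - expected_band_coherence(cfg, "CA1")),
            0.06)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(mixing = list(w_within = 1.2, w_between = 0)),
               class = "gbo_config_error")
  expect_error(sim_config(duration_s = c(vehicle = -1, drug = 10,
                                         antagonist = 5)),
               class = "gbo_config_error")
  expect_error(sim_config(fs_hz = 40,
                          osc = list(CA1 = list(peak_hz = 30,
                                                bandwidth_hz = 5,
                                                amplitude_uv = 1),
                                     CA3 = list(peak_hz = 21,
                                                bandwidth_hz = 5,
                                                amplitude_uv = 1))),
               class = "gbo_config_error")
})
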