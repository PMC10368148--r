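test_that("multitaper PSD satisfies Parseval and localizes sinusoid power", {
  set.seed(101)
  x <- rnorm(30000)
  ps <- multitaper_psd(x, 1000)
  df <- diff(ps$freqs_hz[1:2])
  expect_lt(abs(sum(ps$power) * df / var(x) - 1), 0.05)
  # 40 Hz sinusoid, amplitude 10: total power A^2/2 = 50 uV^2 near 40 Hz
  s <- sine(40, 30, 1000, amp = 10)[-1]
  ps2 <- multitaper_psd(s, 1000)
  nwband <- 3 * 1000 / length(s)
  near <- abs(ps2$freqs_hz - 40) <= nwband + df
  expect_lt(abs(sum(ps2$power[near]) * df - 50) / 50, 0.05)
  # constant signal: power concentrated at DC (within the taper bandwidth)
  psc <- multitaper_psd(rep(3, 2000), 1000)
  dcb <- psc$freqs_hz <= 3 * 1000 / 2000 + df
  expect_gt(sum(psc$power[dcb]) / sum(psc$power), 0.99)
  expect_error(multitaper_psd(1, 1000), class = "gbo_parameter_error")
  expect_error(multitaper_psd(rnorm(100), 1000, nw = 2, k = 5),
               class = "gbo_parameter_error")
})

test_that("band_power integrates the density and is additive over sub-bands", {
  s <- sine(40, 30, 1000, amp = 10)[-1]
  ps <- multitaper_psd(s, 1000)
  expect_lt(abs(band_power(ps, gbo_band()) - 50) / 50, 0.05)
  expect_lt(band_power(ps, gbo_band(2, 20)), 0.5)   # out-of-band sinusoid
  set.seed(7)
  psn <- multitaper_psd(rnorm(60000), 1000)
  expect_lt(abs(band_power(psn, gbo_band()) - (59 - 25) / 500) / 0.068, 0.10)
  # additivity on a shared grid
  whole <- band_power(psn, gbo_band(10, 90))
  parts <- band_power(psn, gbo_band(10, 42)) + band_power(psn, gbo_band(42, 90))
  expect_equal(whole, parts, tolerance = 1e-12)
  expect_error(band_power(psn, gbo_band(400, 600)),
               class = "gbo_parameter_error")
})

test_that("sliding band power tracks stationarity and transitions", {
  fs <- 1000
  x <- sine(40, 60, fs)[-1]
  lfp <- fake_lfp(matrix(rep(x, 60), nrow = 60, byrow = TRUE), fs)
  bp <- sliding_band_power(lfp, window_s = 2, step_s = 1)
  expect_lt(diff(range(bp$power[1, ])) / mean(bp$power[1, ]), 0.05)
  expect_true(all(diff(bp$times_s) > 0))
  # silent-then-oscillating signal steps at the switch time +- window
  y <- c(rep(0, 30 * fs), sine(40, 30, fs)[-1])
  lfp2 <- fake_lfp(matrix(rep(y, 60), nrow = 60, byrow = TRUE), fs)
  bp2 <- sliding_band_power(lfp2, window_s = 2, step_s = 1)
  p <- bp2$power[1, ]
  plateau <- median(p[bp2$times_s > 35])
  t_rise <- bp2$times_s[which(p > 0.5 * plateau)[1]]
  expect_lt(abs(t_rise - 30), 2)
  expect_lt(max(p[bp2$times_s < 28]), 0.01 * plateau)
  # step longer than the record: single window
  bp3 <- sliding_band_power(lfp, window_s = 2, step_s = 120)
  expect_equal(ncol(bp3$power), 1)
  expect_error(sliding_band_power(lfp, window_s = 120),
               class = "gbo_parameter_error")
})

test_that("Morlet spectrogram has the expected ridge, scaling and width", {
  fs <- 1000
  x <- sine(40, 10, fs)[-1]
  sp <- morlet_spectrogram(x, fs, freqs = seq(20, 60, by = 0.25))
  mid <- length(x) %/% 2
  prof <- sp$power[, mid]
  expect_equal(sp$freqs_hz[which.max(prof)], 40)
  # quadratic amplitude scaling
  sp2 <- morlet_spectrogram(2 * x, fs, freqs = seq(20, 60, by = 0.25))
  expect_equal(max(sp2$power[, mid]) / max(prof), 4, tolerance = 1e-6)
  # Gaussian frequency response: amplitude-profile FWHM ~ 2*sqrt(2 ln 2)*sigma_f
  amp <- sqrt(prof / max(prof))
  fw <- range(sp$freqs_hz[amp >= 0.5])
  expect_equal(diff(fw), 2 * sqrt(2 * log(2)) * 40 / 25, tolerance = 0.12)
  # edges are flagged invalid
  expect_true(anyNA(sp$power[1, ]))
  expect_warning(morlet_spectrogram(x[1:500], fs, freqs = c(1, 40)),
                 "dropping")
  expect_error(morlet_spectrogram(x, fs, freqs = c(600)),
               class = "gbo_parameter_error")
})

test_that("peak_and_q implements the half-max bandwidth definition", {
  f <- seq(0, 100, by = 0.5)
  tri <- pmax(0, 1 - abs(f - 30) / 30)     # triangular peak, half-max width 30
  ps <- structure(list(freqs_hz = f, power = tri), class = "gbo_psd")
  pk <- peak_and_q(ps)
  expect_equal(pk$f0, 30)
  expect_equal(pk$B, 30, tolerance = 1e-9)
  expect_equal(pk$Q, 1.0, tolerance = 1e-9)
  # twice the width: Q at the 0.5 periodicity threshold (grid extended so
  # the lower half-max crossing lies inside the spectrum range)
  f2 <- seq(-50, 100, by = 0.5)
  tri2 <- pmax(0, 1 - abs(f2 - 30) / 60)
  ps2 <- structure(list(freqs_hz = f2, power = tri2), class = "gbo_psd")
  expect_equal(peak_and_q(ps2, gbo_band(5, 59))$Q, 0.5, tolerance = 1e-9)
  # Q is invariant to amplitude scaling
  ps3 <- ps; ps3$power <- 7.3 * ps$power
  expect_equal(peak_and_q(ps3)$Q, pk$Q)
  # flat spectrum: no crossings
  flat <- structure(list(freqs_hz = f, power = rep(1, length(f))),
                    class = "gbo_psd")
  expect_error(peak_and_q(flat), class = "gbo_q_undefined")
  expect_error(peak_and_q(ps, gbo_band(5, 400)),
               class = "gbo_parameter_error")
})
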