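test_that("coherence estimator: identity, symmetry, bounds, independence floor", {
  set.seed(21)
  fs <- 1000
  x <- rnorm(60 * fs); y <- rnorm(60 * fs)
  cs_id <- multitaper_coherence(x, x, fs)
  expect_lt(max(abs(cs_id$coherence - 1)), 1e-9)
  cs_xy <- multitaper_coherence(x, y, fs)
  cs_yx <- multitaper_coherence(y, x, fs)
  expect_equal(cs_xy$coherence, cs_yx$coherence)     # symmetry
  expect_true(all(cs_xy$coherence >= 0 & cs_xy$coherence <= 1))
  # independent noise: band coherence near the estimator bias floor
  # E[C] ~ sqrt(pi)/(2 sqrt(nu)), nu = windows x tapers
  nu <- cs_xy$n_segments * 5
  expect_lt(band_coherence(cs_xy), 3 * sqrt(pi) / (2 * sqrt(nu)))
  expect_error(multitaper_coherence(x, y[-1], fs),
               class = "gbo_parameter_error")
})

test_that("shared-source pairs reproduce the analytic coherence and monotonicity", {
  set.seed(22)
  fs <- 1000
  meas <- vapply(c(0.2, 0.5, 0.8), function(rho) {
    p <- shared_noise_pair(90 * fs, fs, rho)
    band_coherence(multitaper_coherence(p$x, p$y, fs))
  }, numeric(1))
  expect_lt(max(abs(meas - c(0.2, 0.5, 0.8))), 0.05)
  expect_true(all(diff(meas) > 0))                   # monotone in rho
})

test_that("band_coherence averages the spectrum over the band", {
  f <- seq(0, 500, by = 0.5)
  cs <- structure(list(freqs_hz = f, coherence = rep(1, length(f))),
                  class = "gbo_coherence")
  expect_equal(band_coherence(cs), 1)
  in_band <- f >= 25 & f <= 59
  half <- rep(0, length(f))
  half[in_band][seq_len(floor(sum(in_band) / 2))] <- 1
  cs$coherence <- half
  expect_equal(band_coherence(cs), 0.5, tolerance = 0.02)
  expect_error(band_coherence(cs, gbo_band(400, 600)),
               class = "gbo_parameter_error")
})

test_that("pairwise_table enumerates region pairs with the right combinatorics", {
  set.seed(23)
  fs <- 500
  lay <- make_layout()           # 30 CA1, 29 CA3 (+1 reference on CA3 side)
  lfp <- fake_lfp(matrix(rnorm(60 * 20 * fs), nrow = 60), fs, lay)
  pt <- pairwise_table(lfp, band = gbo_band(25, 59), window_s = 1)
  n_ca1 <- 30; n_ca3 <- 29
  expect_equal(nrow(pt), choose(n_ca1 + n_ca3, 2))
  tab <- table(pt$region_pair)
  expect_equal(unname(tab[["within_CA1"]]), choose(n_ca1, 2))
  expect_equal(unname(tab[["within_CA3"]]), choose(n_ca3, 2))
  expect_equal(unname(tab[["between_CA1_CA3"]]), n_ca1 * n_ca3)
  expect_true(all(pt$elec1 < pt$elec2))
  expect_true(all(pt$coh_drug >= 0 & pt$coh_drug <= 1))
  # all-CA1 layout: only within_CA1 records (region warning emitted)
  lay1 <- make_layout(region_split = 0)
  lfp1 <- fake_lfp(lfp$data, fs, lay1)
  expect_warning(pt1 <- pairwise_table(lfp1, band = gbo_band(25, 59),
                                       window_s = 1), "CA3")
  expect_true(all(pt1$region_pair == "within_CA1"))
})

test_that("power correlation map has exact trivial structure", {
  set.seed(24)
  env <- abs(rnorm(100)) + 1
  pow <- rbind(env, 2 * env, max(env) + 1 - env, matrix(rexp(100 * 3), 3))
  lfp <- fake_lfp(matrix(0, 6, 100))
  bp <- structure(list(times_s = 1:100, power = pow), class = "gbo_bandpower")
  r <- power_correlation_map(bp)
  expect_equal(unname(diag(r)), rep(1, 6))
  expect_equal(r[1, 2], 1)                  # duplicated (scaled) channel
  expect_equal(r[1, 3], -1)                 # sign-flipped envelope
  expect_equal(r, t(r))
  # zero-variance channel flagged
  bp$power[4, ] <- 5
  expect_warning(r2 <- power_correlation_map(bp), "zero-variance")
  expect_true(all(is.na(r2[4, -4])))
})

test_that("independent envelopes have small correlations at n = 100", {
  set.seed(25)
  bp <- structure(list(times_s = 1:100,
                       power = matrix(rexp(30 * 100), nrow = 30)),
                  class = "gbo_bandpower")
  r <- power_correlation_map(bp)
  off <- abs(r[upper.tri(r)])
  expect_gt(mean(off <= 0.3), 0.98)
})

test_that("graph edges respect the inclusive 0.45 threshold and monotonicity", {
  lay <- make_layout()
  rec <- data.frame(slice_id = "s", elec1 = c(0, 1, 2), elec2 = c(1, 2, 3),
                    region_pair = "within_CA3",
                    coh_vehicle = c(0.1, 0.2, 0.3),
                    coh_drug = c(0.45, 0.449, 0.9))
  rec$fold_change <- rec$coh_drug / rec$coh_vehicle
  g <- build_graph(rec, lay, condition = "drug")
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 2)                      # 0.45 in, 0.449 out
  expect_true(all(el$weight >= 0.45))
  expect_setequal(igraph::V(g)$name, as.character(0:3))
  # non-increasing edge count in threshold
  counts <- vapply(seq(0, 1, by = 0.1), function(th)
    igraph::ecount(build_graph(rec, lay, condition = "drug",
                               threshold = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # all-zero coherence: edgeless graph retains nodes
  rec0 <- rec; rec0$coh_drug <- 0
  g0 <- build_graph(rec0, lay, condition = "drug")
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 4)
})
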