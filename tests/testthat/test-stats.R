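test_that("fit_lme recovers the generative parameters of a single draw", {
  set.seed(41)
  d <- simulate_lme_records()
  m <- fit_lme(d)
  expect_equal(m$fixed$name[1], "(Intercept)")
  expect_lt(abs(m$fixed$estimate[1] - 1.231), 3 * m$fixed$se[1])
  i_btw <- m$fixed$name == "Regionsbetween_CA1_CA3"
  expect_lt(abs(m$fixed$estimate[i_btw] - (-0.104)), 3 * m$fixed$se[i_btw])
  expect_equal(m$fixed$df[1], m$n_obs - 3)
  expect_equal(m$n_groups[["Slice"]], 11)
  expect_true(all(m$random$sd >= 0))
})

test_that("with zero random variance the fixed effects equal group-mean contrasts", {
  set.seed(42)
  d <- simulate_lme_records(n_slices = 4, n_per_region = 6,
                            sd_slice = 0, sd_elec = 0, sd_resid = 0.1)
  m <- fit_lme(d)
  mm <- tapply(d$fold_change, d$region_pair, mean)
  expect_equal(m$fixed$estimate[1], unname(mm["within_CA3"]),
               tolerance = 1e-6)
  expect_equal(m$fixed$estimate[m$fixed$name == "Regionswithin_CA1"],
               unname(mm["within_CA1"] - mm["within_CA3"]), tolerance = 1e-6)
  expect_equal(m$fixed$estimate[m$fixed$name == "Regionsbetween_CA1_CA3"],
               unname(mm["between_CA1_CA3"] - mm["within_CA3"]),
               tolerance = 1e-6)
})

test_that("the ML fit dominates the no-random-effect model and ignores slice labels", {
  set.seed(43)
  d <- simulate_lme_records(n_slices = 5, n_per_region = 5)
  m <- fit_lme(d)
  lm0 <- stats::lm(fold_change ~ factor(region_pair,
                                        levels = gbokit:::REGION_LEVELS),
                   data = d)
  expect_gte(m$logLik, as.numeric(stats::logLik(lm0)) - 1e-6)
  # relabeling slices leaves fixed effects unchanged
  d2 <- d
  d2$slice_id <- factor(d$slice_id,
                        labels = sample(LETTERS[1:5]))
  m2 <- fit_lme(d2)
  expect_equal(m2$fixed$estimate, m$fixed$estimate, tolerance = 1e-6)
})

test_that("degenerate designs raise informative errors", {
  set.seed(44)
  d <- simulate_lme_records(n_slices = 4, n_per_region = 4)
  expect_error(fit_lme(d[d$slice_id == "s01", ]),
               class = "gbo_parameter_error")
  d$Transected <- 1L
  expect_error(fit_lme(d, fixed = c("Regions", "Transected")),
               "levels", class = "gbo_parameter_error")
  # aliased predictor: Model duplicates Transected
  d$Transected <- as.integer(d$slice_id %in% c("s01", "s02"))
  d$Model <- d$Transected
  expect_error(fit_lme(d, fixed = c("Regions", "Transected", "Model")),
               "aliased", class = "gbo_parameter_error")
})

test_that("interaction models estimate group x region effects", {
  set.seed(45)
  d <- simulate_lme_records(
    n_slices = 8, n_per_region = 8,
    group = list(name = "Transected",
                 effects = c(main = 0, within_CA1 = 0, between = -0.4)))
  m <- fit_lme(d, fixed = c("Regions", "Transected"), interaction = TRUE)
  nm <- m$fixed$name
  i <- grepl("Transected1:Regionsbetween", nm)
  expect_true(any(i))
  expect_lt(m$fixed$estimate[i], 0)
  expect_lt(m$fixed$p[i], 0.01)
})

test_that("nonparametric battery dispatches by design", {
  set.seed(46)
  # paired identical samples: degenerate, p = 1
  x <- rnorm(10)
  r <- nonparametric_battery(list(a = x, b = x), design = "paired")
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
  r2 <- nonparametric_battery(list(a = x, b = x + rnorm(10, 2)),
                              design = "paired")
  expect_equal(r2$test, "wilcoxon_signed_rank")
  expect_lt(r2$p, 0.05)
  # two unpaired groups: KS
  r3 <- nonparametric_battery(list(a = rnorm(50), b = rnorm(50, 5)))
  expect_equal(r3$test, "kolmogorov_smirnov")
  expect_lt(r3$p, 0.001)
  # three identical groups: H ~ 0
  g <- list(a = 1:9, b = 1:9, c = 1:9)
  r4 <- nonparametric_battery(g)
  expect_equal(r4$statistic[r4$test == "kruskal_wallis"], 0, tolerance = 1e-9)
  expect_equal(nrow(r4), 1 + 3)            # omnibus + 3 Dunn comparisons
  expect_error(nonparametric_battery(list(a = 1:2, b = 1:5)),
               class = "gbo_parameter_error")
})

test_that("model_report reproduces the table identities", {
  set.seed(47)
  d <- simulate_lme_records(n_slices = 4, n_per_region = 5)
  m <- fit_lme(d)
  rep <- model_report(m)
  expect_equal(m$deviance, -2 * m$logLik, tolerance = 1e-6)
  expect_equal(m$AIC, m$deviance + 2 * (nrow(m$fixed) + 3),
               tolerance = 1e-6)
  expect_equal(rep$fixed$name[1], "(Intercept)")
  expect_true(any(grepl("Fixed effects", rep$markdown)))
  expect_equal(rep$info$value[rep$info$quantity == "n_obs"], m$n_obs)
})

test_that("MAD outlier screen removes only extreme rows and is off by default", {
  set.seed(48)
  d <- simulate_lme_records(n_slices = 3, n_per_region = 4)
  d$fold_change[1] <- 1e3
  kept <- exclude_outliers_mad(d)
  expect_equal(nrow(kept), nrow(d) - 1)
  expect_false(1e3 %in% kept$fold_change)
})
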