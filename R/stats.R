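REGION_LEVELS <- c("within_CA3", "within_CA1", "between_CA1_CA3")

#' Linear mixed-effects model of coherence by region pair
#'
#' Fits `response ~ 1 + <fixed terms> + (1 | Slice) + (1 | Slice:Elec1)` by
#' maximum likelihood: random intercepts for slice and for the first
#' electrode of each pair nested in slice. `Regions` is a three-level factor
#' (reference `within_CA3`, then `within_CA1`, then `between_CA1_CA3`);
#' optional binary predictors `Transected` or `Model` (genotype) may be
#' added, with interaction. Wald t tests use residual degrees of freedom
#' `n_obs - n_fixed` (null hypothesis: coefficient equals zero).
#'
#' @param records data.frame with columns `slice_id`, `elec1`,
#'   `region_pair`, the response column, and any extra binary predictor
#' @param fixed character vector of fixed predictors among
#'   `"Regions"`, `"Transected"`, `"Model"`
#' @param interaction if `TRUE` and a second predictor is present, include
#'   its interaction with `Regions`
#' @param response name of the response column (default `"fold_change"`,
#'   the drug/vehicle change in band coherence; `"coh_drug"` gives raw
#'   drug-condition coherence)
#' @return list of class `gbo_lme` with elements `fixed` (data.frame:
#'   name, estimate, se, t, df, p, lower, upper), `random` (group, sd),
#'   `logLik`, `deviance`, `AIC`, `BIC`, `n_obs`, `n_groups`, `formula`,
#'   and the underlying `lme4` fit as `fit`
#' @export
fit_lme <- function(records, fixed = "Regions", interaction = FALSE,
                    response = "fold_change") {
  df <- data.frame(
    y = records[[response]],
    Slice = factor(records$slice_id),
    Elec1 = factor(paste(records$slice_id, records$elec1, sep = ":")))
  if (nlevels(df$Slice) < 2)
    .gbo_error("random slice intercept inestimable with a single slice",
               "gbo_parameter_error")
  terms <- character()
  if ("Regions" %in% fixed) {
    df$Regions <- factor(records$region_pair, levels = REGION_LEVELS)
    df$Regions <- droplevels(df$Regions)
    terms <- c(terms, "Regions")
  }
  for (extra in intersect(c("Transected", "Model"), fixed)) {
    df[[extra]] <- factor(records[[extra]])
    if (nlevels(df[[extra]]) < 2)
      .gbo_error(sprintf("predictor %s has fewer than 2 observed levels",
                         extra), "gbo_parameter_error")
    terms <- c(terms,
               if (interaction && "Regions" %in% fixed)
                 sprintf("%s * Regions", extra) else extra)
  }
  if (interaction && length(terms) > 1) terms <- setdiff(terms, "Regions")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fixed_formula <- stats::as.formula(paste("y ~ 1 +", rhs))
  X <- model.matrix(fixed_formula, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    .gbo_error(paste("rank-deficient fixed design; aliased term(s):",
                     paste(aliased, collapse = ", ")),
               "gbo_parameter_error")
  }
  form <- stats::as.formula(
    paste("y ~ 1 +", rhs, "+ (1 | Slice) + (1 | Slice:Elec1)"))
  fit <- lme4::lmer(form, data = df, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_obs <- nrow(df)
  dof <- n_obs - length(beta)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), dof)
  crit <- stats::qt(0.975, dof)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(g) vc$sdcor[vc$grp == g][1]
  ll <- as.numeric(stats::logLik(fit))
  out <- list(
    fixed = data.frame(name = names(beta), estimate = as.numeric(beta),
                       se = se, t = tval, df = dof, p = pval,
                       lower = beta - crit * se, upper = beta + crit * se,
                       row.names = NULL),
    random = data.frame(
      group = c("Slice", "Slice:Elec1", "Residual"),
      sd = c(sd_of("Slice"), sd_of("Slice:Elec1"), sd_of("Residual"))),
    logLik = ll, deviance = -2 * ll,
    AIC = stats::AIC(fit), BIC = stats::BIC(fit),
    n_obs = n_obs,
    n_groups = c(Slice = nlevels(df$Slice),
                 `Slice:Elec1` = length(unique(paste(df$Slice, df$Elec1)))),
    formula = form, fit = fit)
  class(out) <- "gbo_lme"
  out
}

#' @export
print.gbo_lme <- function(x, ...) {
  cat("Linear mixed-effects model fit by ML\n")
  cat(deparse(x$formula), "\n")
  cat(sprintf("n_obs = %d; AIC = %.1f; logLik = %.2f\n",
              x$n_obs, x$AIC, x$logLik))
  print(x$fixed, digits = 3)
  print(x$random, digits = 3)
  invisible(x)
}

#' Simulate coherence records from the mixed-model generative process
#'
#' Draws a pair table with the assay's nested design: per slice,
#' electrodes split between CA1 and CA3, all unordered pairs enumerated
#' (`elec1` = the lower id, nested in slice), and
#' `y = X beta + u_slice + u_elec1 + e`. Used for parameter-recovery and
#' type-I-error studies of [fit_lme()].
#'
#' @param n_slices number of slices (default 11, a typical assay size)
#' @param n_per_region electrodes per region per slice (12 gives ~276
#'   pairs/slice, ~300 observations per slice)
#' @param beta named effects: `intercept`, `within_CA1`, `between`
#'   (contrasts vs the within-CA3 reference)
#' @param sd_slice,sd_elec,sd_resid random-effect standard deviations
#' @param group optional list(name =, effects =) to add a binary predictor:
#'   slices are split between level 0 and 1, `effects` is a named vector
#'   `c(main =, within_CA1 =, between =)` added for level-1 slices
#' @return data.frame usable by [fit_lme()] (response column `fold_change`)
#' @export
simulate_lme_records <- function(n_slices = 11, n_per_region = 12,
                                 beta = c(intercept = 1.231,
                                          within_CA1 = 0.031,
                                          between = -0.104),
                                 sd_slice = 0.171, sd_elec = 0.141,
                                 sd_resid = 0.175, group = NULL) {
  rows <- list()
  for (s in seq_len(n_slices)) {
    n_e <- 2 * n_per_region
    region <- rep(c("CA1", "CA3"), each = n_per_region)
    pr <- utils::combn(n_e, 2)
    rp <- vapply(seq_len(ncol(pr)), function(q)
      region_pair_label(region[pr[1, q]], region[pr[2, q]]), character(1))
    u_s <- rnorm(1, 0, sd_slice)
    u_e <- rnorm(n_e, 0, sd_elec)
    mu <- beta[["intercept"]] +
      ifelse(rp == "within_CA1", beta[["within_CA1"]], 0) +
      ifelse(rp == "between_CA1_CA3", beta[["between"]], 0)
    g_lvl <- 0L
    if (!is.null(group)) {
      g_lvl_all <- rep(0:1, length.out = n_slices)
      g_lvl <- g_lvl_all[s]
      if (g_lvl == 1) {
        ef <- group$effects
        mu <- mu + ef[["main"]] +
          ifelse(rp == "within_CA1", ef[["within_CA1"]], 0) +
          ifelse(rp == "between_CA1_CA3", ef[["between"]], 0)
      }
    }
    y <- mu + u_s + u_e[pr[1, ]] + rnorm(ncol(pr), 0, sd_resid)
    rows[[s]] <- data.frame(
      slice_id = sprintf("s%02d", s), elec1 = pr[1, ], elec2 = pr[2, ],
      region_pair = rp, fold_change = y,
      stringsAsFactors = FALSE)
    if (!is.null(group)) rows[[s]][[group$name]] <- g_lvl
  }
  do.call(rbind, rows)
}

#' Nonparametric test battery
#'
#' Dispatches by design: Wilcoxon signed-rank for paired data,
#' Kolmogorov-Smirnov for two unpaired groups, Kruskal-Wallis followed by
#' Dunn's multiple comparisons for three or more groups.
#'
#' @param groups named list of numeric vectors
#' @param design `"paired"`, `"unpaired"` or `"auto"` (unpaired)
#' @return data.frame of comparisons: test, comparison, statistic, p
#'   (Dunn's p values are Bonferroni-adjusted over the comparison family);
#'   degenerate paired data (all differences zero) are flagged
#' @export
nonparametric_battery <- function(groups, design = c("auto", "paired",
                                                     "unpaired")) {
  design <- match.arg(design)
  if (any(vapply(groups, length, 1L) < 3))
    .gbo_error("all groups need at least 3 observations",
               "gbo_parameter_error")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  if (design == "paired") {
    if (length(groups) != 2)
      .gbo_error("paired design needs exactly 2 groups",
                 "gbo_parameter_error")
    d <- groups[[1]] - groups[[2]]
    if (all(d == 0))
      return(data.frame(test = "wilcoxon_signed_rank",
                        comparison = paste(nm, collapse = " vs "),
                        statistic = 0, p = 1, degenerate = TRUE))
    w <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
                                      paired = TRUE, exact = FALSE))
    return(data.frame(test = "wilcoxon_signed_rank",
                      comparison = paste(nm, collapse = " vs "),
                      statistic = unname(w$statistic), p = w$p.value,
                      degenerate = FALSE))
  }
  if (length(groups) == 2) {
    ks <- suppressWarnings(ks.test(groups[[1]], groups[[2]]))
    return(data.frame(test = "kolmogorov_smirnov",
                      comparison = paste(nm, collapse = " vs "),
                      statistic = unname(ks$statistic), p = ks$p.value,
                      degenerate = FALSE))
  }
  kw <- kruskal.test(groups)
  out <- data.frame(test = "kruskal_wallis", comparison = "omnibus",
                    statistic = unname(kw$statistic), p = kw$p.value,
                    degenerate = FALSE)
  rbind(out, dunn_test(groups, nm))
}

# Dunn's z tests on mean ranks with tie correction; Bonferroni-adjusted p
dunn_test <- function(groups, nm = names(groups)) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  cmb <- utils::combn(length(groups), 2)
  res <- lapply(seq_len(ncol(cmb)), function(q) {
    i <- cmb[1, q]; j <- cmb[2, q]
    z <- (rbar[i] - rbar[j]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    data.frame(test = "dunn", comparison = paste(nm[i], "vs", nm[j]),
               statistic = unname(z),
               p = min(1, 2 * pnorm(-abs(z)) * ncol(cmb)),
               degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Format a fitted mixed model as a report table
#'
#' Reproduces the standard report layout: model information, fit statistics
#' (AIC, BIC, log-likelihood, deviance), fixed-effect coefficients with 95%
#' CIs and Wald t tests, and random-effect standard deviations (with profile
#' CIs when `ci_random = TRUE`).
#'
#' @param result a `gbo_lme`
#' @param ci_random compute profile-likelihood CIs for the random-effect
#'   SDs (slower; Wald fixed-effect CIs are always included)
#' @param path optional CSV path for the fixed-effects table
#' @return list with `info`, `fit_stats`, `fixed`, `random` data.frames and
#'   `markdown` (character vector of report lines)
#' @export
model_report <- function(result, ci_random = FALSE, path = NULL) {
  info <- data.frame(
    quantity = c("n_obs", "fixed_effects", "covariance_parameters",
                 "slices", "elec1_groups"),
    value = c(result$n_obs, nrow(result$fixed), 3,
              result$n_groups[["Slice"]],
              result$n_groups[["Slice:Elec1"]]))
  fit_stats <- data.frame(AIC = result$AIC, BIC = result$BIC,
                          logLik = result$logLik,
                          deviance = result$deviance)
  random <- result$random
  if (ci_random) {
    ci <- tryCatch(stats::confint(result$fit, parm = "theta_",
                                  method = "profile", quiet = TRUE),
                   error = function(e) NULL)
    if (!is.null(ci)) {
      random$lower <- c(ci["sd_(Intercept)|Slice", 1],
                        ci["sd_(Intercept)|Slice:Elec1", 1],
                        ci[".sigma", 1])
      random$upper <- c(ci["sd_(Intercept)|Slice", 2],
                        ci["sd_(Intercept)|Slice:Elec1", 2],
                        ci[".sigma", 2])
    }
  }
  md <- c("## Linear mixed-effects model (ML)",
          paste("Formula:", deparse(result$formula)),
          "", "### Fit statistics",
          sprintf("AIC %.2f | BIC %.2f | logLik %.2f | deviance %.2f",
                  result$AIC, result$BIC, result$logLik, result$deviance),
          "", "### Fixed effects (95% CIs)",
          utils::capture.output(print(result$fixed, digits = 4)),
          "", "### Random-effect standard deviations",
          utils::capture.output(print(random, digits = 4)))
  if (!is.null(path)) write.csv(result$fixed, path, row.names = FALSE)
  list(info = info, fit_stats = fit_stats, fixed = result$fixed,
       random = random, markdown = md)
}

#' Optional simple outlier exclusion for coherence records
#'
#' Robust-regression outlier removal (as used for figure-level cleaning in
#' some analysis suites) is proprietary; this documented substitute flags
#' observations farther than `k` median absolute deviations from the median
#' of their region-pair group. Off by default everywhere.
#'
#' @param records a [pairwise_table()] data.frame
#' @param response column to screen
#' @param k MAD multiplier (default 5)
#' @return records with outlier rows removed
#' @export
exclude_outliers_mad <- function(records, response = "fold_change", k = 5) {
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$region_pair),
                        function(ix) {
    v <- records[[response]][ix]
    m <- median(v); s <- stats::mad(v)
    if (s == 0) return(ix)
    ix[abs(v - m) <= k * s]
  }))
  records[sort(keep), ]
}
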