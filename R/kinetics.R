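sigmoid4 <- function(t_min, a, b, c, d) c / (1 + exp(-a * t_min + a * b)) + d

#' Fit a four-parameter sigmoid to a band-power time course
#'
#' Nonlinear least squares of `c / (1 + exp(-a*(t - b))) + d` with `t` in
#' minutes: `a` is the slope (1/min), `b` the midpoint (min), `c` the
#' amplitude and `d` the baseline (both microvolt^2). Default starting
#' values follow the usual heuristic (`d` = min, `c` = range, `b` = time of
#' half-maximum, `a` from the 10-90% rise interval); pass `init` to override,
#' mirroring manual initialization on real recordings. Fits that fail to
#' converge or return `a <= 0` or `c <= 0` are flagged `converged = FALSE`
#' and excluded downstream.
#'
#' @param times_s sample times, seconds (e.g. band-power window centers,
#'   relative to drug onset)
#' @param power band power values
#' @param window optional `[t0, t1)` fit window in seconds
#' @param init optional named list/vector with `a`, `b`, `c`, `d`
#' @return list of class `gbo_sigmoid_fit`: `a`, `b`, `c`, `d`, `rss`,
#'   `converged`, `fit_window`
#' @export
fit_sigmoid <- function(times_s, power, window = NULL, init = NULL) {
  if (!is.null(window)) {
    keep <- times_s >= window[1] & times_s < window[2]
    times_s <- times_s[keep]; power <- power[keep]
  }
  if (length(times_s) == 0)
    .gbo_error("empty fit window", "gbo_parameter_error")
  if (length(times_s) < 8)
    .gbo_error("need at least 8 samples in the fit window",
               "gbo_parameter_error")
  x <- times_s / 60
  fail <- function() structure(
    list(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
         rss = NA_real_, converged = FALSE,
         fit_window = range(times_s)), class = "gbo_sigmoid_fit")
  if (is.null(init)) {
    d0 <- min(power); c0 <- max(power) - d0
    if (c0 <= 0) return(fail())
    above <- function(q) {
      i <- which(power >= d0 + q * c0)[1]
      if (is.na(i)) x[length(x)] else x[i]
    }
    t10 <- above(0.1); t50 <- above(0.5); t90 <- above(0.9)
    a0 <- if (t90 > t10) 4 / (t90 - t10) else 1
    init <- list(a = a0, b = t50, c = c0, d = d0)
  }
  fit <- tryCatch(
    nls(power ~ c / (1 + exp(-a * x + a * b)) + d,
        start = init, algorithm = "port",
        lower = c(a = 1e-6, b = -Inf, c = 1e-12, d = -Inf),
        control = list(warnOnly = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(fail())
  cf <- coef(fit)
  if (cf[["a"]] <= 0 || cf[["c"]] <= 0) return(fail())
  structure(list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]], d = cf[["d"]],
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 fit_window = range(times_s)),
            class = "gbo_sigmoid_fit")
}

#' Onset latency: time to 90% of maximum (GBO90)
#'
#' Closed-form solution of `c/(1 + exp(-a*(t - b))) + d = 0.9*(c + d)`:
#' `t = b - (1/a) * log(c / (0.9*(c + d) - d) - 1)`. The "maximum" is the
#' fitted asymptote `c + d`, not the noisy sample maximum.
#'
#' @param fit a converged `gbo_sigmoid_fit`
#' @return onset latency in minutes
#' @export
gbo90 <- function(fit) {
  if (!isTRUE(fit$converged))
    .gbo_error("gbo90 requires a converged fit", "gbo_kinetics_undefined")
  thr <- 0.9 * (fit$c + fit$d)
  if (thr <= fit$d)
    .gbo_error("90% threshold not above baseline; onset undefined",
               "gbo_kinetics_undefined")
  arg <- fit$c / (thr - fit$d) - 1
  if (arg <= 0)
    .gbo_error("fitted asymptote below the 90% threshold; onset undefined",
               "gbo_kinetics_undefined")
  fit$b - log(arg) / fit$a
}

#' Offset kinetics: 90-to-10% fall interval and GBO10
#'
#' Thresholds are `d' + 0.9*(max - d')` and `d' + 0.1*(max - d')` with
#' `max`/`d'` the window maximum/minimum. Crossing times are found by linear
#' interpolation between samples on the last falling pass; `gbo90_10` is the
#' 90%-to-10% interval and `gbo10` the 10% crossing time relative to
#' `t_ref_s` (typically antagonist onset).
#'
#' @param times_s,power the band-power time course
#' @param window optional `[t0, t1)` restriction, seconds
#' @param t_ref_s reference time subtracted from the 10% crossing
#' @return list with `gbo90_10` (s) and `gbo10` (s)
#' @export
fall_interval <- function(times_s, power, window = NULL, t_ref_s = 0) {
  if (!is.null(window)) {
    keep <- times_s >= window[1] & times_s < window[2]
    times_s <- times_s[keep]; power <- power[keep]
  }
  if (length(power) < 3)
    .gbo_error("too few samples for fall-time analysis",
               "gbo_parameter_error")
  d0 <- min(power); mx <- max(power)
  hi <- d0 + 0.9 * (mx - d0); lo <- d0 + 0.1 * (mx - d0)
  cross_down <- function(thr) {
    idx <- which(power[-length(power)] >= thr & power[-1] < thr)
    if (length(idx) == 0) return(NA_real_)
    i <- idx[length(idx)]            # last falling pass
    times_s[i] + (power[i] - thr) / (power[i] - power[i + 1]) *
      (times_s[i + 1] - times_s[i])
  }
  t_lo <- cross_down(lo)
  if (is.na(t_lo))
    .gbo_error("series never falls below the 10% threshold",
               "gbo_kinetics_undefined")
  t_hi_candidates <- times_s[power >= hi]
  t_hi <- cross_down(hi)
  if (is.na(t_hi) || t_hi > t_lo) t_hi <- max(t_hi_candidates)
  list(gbo90_10 = t_lo - t_hi, gbo10 = t_lo - t_ref_s)
}

#' Fractional change in oscillatory power
#'
#' `(P_drug - P_vehicle) / P_vehicle`, computed from band power in the final
#' stretch of each condition; negative values indicate suppression (an
#' antagonist that halves gamma power scores about -0.5).
#'
#' @param p_drug,p_vehicle band power in the drug and reference conditions
#' @return unitless fractional change
#' @export
fractional_power_change <- function(p_drug, p_vehicle) {
  if (any(p_vehicle <= 0))
    .gbo_error("reference power must be positive", "gbo_kinetics_undefined")
  (p_drug - p_vehicle) / p_vehicle
}

#' Per-channel kinetics table for a recording
#'
#' Runs the sigmoid onset fit on the drug epoch, the fall-time analysis on
#' the drug-end + antagonist window, and the fractional power change
#' (final fraction of drug vs vehicle), returning one row per
#' non-reference electrode.
#'
#' @param bp a `gbo_bandpower` from [sliding_band_power()]
#' @param drug_epoch,antagonist_epoch,vehicle_epoch epoch labels
#' @param tail_frac fraction of each epoch used for "final minutes" power
#'   summaries (default 0.5 of the scaled epochs; the full-length protocol
#'   uses the final 5 of 60 min)
#' @param fall_lead_s how much of the late drug epoch precedes the
#'   antagonist window in the fall-time analysis
#' @return data.frame with columns channel, region, slice_id, gbo90_min,
#'   gbo10_s, gbo90_10_s, frac_change, fit_ok
#' @export
kinetics_table <- function(bp, drug_epoch = "kainate",
                           antagonist_epoch = "kainate_bicuculline",
                           vehicle_epoch = "vehicle",
                           tail_frac = 0.5, fall_lead_s = NULL) {
  ep <- function(lab) bp$epochs[bp$epochs$label == lab, ]
  dr <- ep(drug_epoch); an <- ep(antagonist_epoch); ve <- ep(vehicle_epoch)
  lay <- bp$layout
  keep <- !lay$is_reference
  if (is.null(fall_lead_s))
    fall_lead_s <- min(120, 0.2 * (dr$t_end_s - dr$t_start_s))
  rows <- lapply(which(keep), function(k) {
    ch <- lay$electrode_id[k]
    p <- bp$power[ch + 1L, ]
    tt <- bp$times_s
    in_drug <- tt >= dr$t_start_s & tt < dr$t_end_s
    fit <- fit_sigmoid(tt[in_drug] - dr$t_start_s, p[in_drug])
    g90 <- if (fit$converged)
      tryCatch(gbo90(fit), gbo_error = function(e) NA_real_) else NA_real_
    fall <- tryCatch(
      fall_interval(tt, p,
                    window = c(an$t_start_s - fall_lead_s, an$t_end_s),
                    t_ref_s = an$t_start_s),
      gbo_error = function(e) list(gbo90_10 = NA_real_, gbo10 = NA_real_))
    tail_of <- function(e) {
      w <- tt >= e$t_end_s - tail_frac * (e$t_end_s - e$t_start_s) &
        tt < e$t_end_s
      mean(p[w])
    }
    fc <- tryCatch(fractional_power_change(tail_of(dr), tail_of(ve)),
                   gbo_error = function(e) NA_real_)
    data.frame(channel = ch, region = as.character(lay$region[k]),
               slice_id = bp$slice_id, gbo90_min = g90,
               gbo10_s = fall$gbo10, gbo90_10_s = fall$gbo90_10,
               frac_change = fc, fit_ok = fit$converged)
  })
  do.call(rbind, rows)
}
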