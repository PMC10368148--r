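# -- IIR design -------------------------------------------------------------

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0) - c(0, p * rk)
  p
}

#' Digital low-pass Butterworth filter coefficients
#'
#' Standard bilinear-transform design of an order-`order` analog Butterworth
#' prototype (unit DC gain).
#'
#' @param order filter order
#' @param cutoff_hz -3 dB cutoff frequency
#' @param fs_hz sampling rate; `cutoff_hz` must be below Nyquist
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1)
#' @export
butter_lowpass <- function(order, cutoff_hz, fs_hz) {
  if (cutoff_hz >= fs_hz / 2)
    .gbo_error("cutoff must be below the Nyquist frequency",
               "gbo_parameter_error")
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # left half-plane
  wc <- 2 * fs_hz * tan(pi * cutoff_hz / fs_hz)          # pre-warped
  sp <- wc * p
  gain <- wc^order
  zp <- (2 * fs_hz + sp) / (2 * fs_hz - sp)              # bilinear transform
  kz <- Re(gain / prod(2 * fs_hz - sp))
  b <- Re(poly_from_roots(rep(-1 + 0i, order))) * kz
  a <- Re(poly_from_roots(zp))
  list(b = b / a[1] * 1, a = a / a[1])
}

# steady-state initial filter state for a unit-amplitude input
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  # companion matrix of a, transposed
  A <- rbind(-a[-1], cbind(diag(n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward then backward with odd-reflection padding and
#' steady-state initial conditions, so the effective magnitude response is
#' squared and the phase response is zero.
#'
#' @param b,a filter coefficients, e.g. from [butter_lowpass()]
#' @param x signal vector
#' @param padlen reflection pad length (default scales with the filter's
#'   impulse-response duration)
#' @return filtered vector, same length as `x`
#' @export
filtfilt_zero_phase <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 3 * (max(length(a), length(b)) - 1) * 10
  padlen <- min(padlen, n - 1)
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- .iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- .iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Low-pass filter a recording to isolate the LFP
#'
#' Per-channel zero-phase Butterworth low-pass at `cutoff_hz` (order
#' `order` applied forward-backward, i.e. effective order `2*order`); DC and
#' phase are preserved, as required for downstream coherence analysis.
#'
#' @param rec a `gbo_recording`
#' @param cutoff_hz cutoff (default 100)
#' @param order one-pass filter order (default 4)
#' @return a `gbo_recording` with filtered data and filter provenance
#' @export
lowpass_lfp <- function(rec, cutoff_hz = 100, order = 4) {
  des <- butter_lowpass(order, cutoff_hz, rec$fs_hz)
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- filtfilt_zero_phase(des$b, des$a, rec$data[ch, ])
  out$provenance <- c(rec$provenance, list(filter_spec = list(
    type = "butterworth_lowpass_zerophase", order = order,
    cutoff_hz = cutoff_hz)))
  out
}

#' Downsample a low-pass-filtered recording to the LFP rate
#'
#' Integer-factor decimation (sample picking); the caller is expected to have
#' applied [lowpass_lfp()] first (done automatically when no filter
#' provenance is present). Epoch timestamps, in seconds, are unchanged.
#'
#' @param rec a `gbo_recording`
#' @param target_fs target sampling rate; must divide `rec$fs_hz`
#' @return object of class `gbo_lfp` (a `gbo_recording` at `target_fs`)
#' @export
downsample <- function(rec, target_fs = 1000) {
  factor <- rec$fs_hz / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    .gbo_error(sprintf("fs %g is not an integer multiple of target %g",
                       rec$fs_hz, target_fs), "gbo_parameter_error")
  factor <- as.integer(round(factor))
  if (is.null(rec$provenance$filter_spec) && factor > 1)
    rec <- lowpass_lfp(rec)
  n_out <- floor(ncol(rec$data) / factor)
  idx <- seq.int(1L, by = factor, length.out = n_out)
  out <- rec
  out$data <- rec$data[, idx, drop = FALSE]
  out$fs_hz <- target_fs
  out$provenance <- c(rec$provenance,
                      list(decimation_factor = factor,
                           interpolated_segments = list()))
  class(out) <- c("gbo_lfp", "gbo_recording")
  out
}

#' Linear interpolation over artifact segments
#'
#' Replaces samples inside each `[t0, t1)` segment by the straight line
#' joining the last sample before the segment to the first sample after it,
#' mirroring manual cleaning of transient noise in the gamma band.
#'
#' @param lfp a `gbo_lfp` (or any `gbo_recording`)
#' @param segments data.frame with columns `channel` (electrode id, 0-based),
#'   `t0_s`, `t1_s`
#' @param max_len_s maximum segment length accepted (default 5 s)
#' @return the recording with interpolated data and updated provenance
#' @export
interpolate_artifacts <- function(lfp, segments, max_len_s = 5) {
  if (nrow(segments) == 0) return(lfp)
  fs <- lfp$fs_hz
  n <- ncol(lfp$data)
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    if (seg$t1_s - seg$t0_s > max_len_s)
      .gbo_error("artifact segment exceeds maximum length",
                 "gbo_parameter_error")
    i0 <- floor(seg$t0_s * fs) + 1L
    i1 <- ceiling(seg$t1_s * fs)
    if (i0 <= 1 || i1 >= n)
      .gbo_error("artifact segment touches the record boundary (no anchor)",
                 "gbo_parameter_error")
    ch <- seg$channel + 1L
    anchor_l <- lfp$data[ch, i0 - 1L]
    anchor_r <- lfp$data[ch, i1 + 1L]
    k <- seq.int(i0, i1)
    lfp$data[ch, k] <- anchor_l +
      (anchor_r - anchor_l) * (k - (i0 - 1L)) / (i1 + 1L - (i0 - 1L))
  }
  lfp$provenance$interpolated_segments <-
    c(lfp$provenance$interpolated_segments,
      split(segments, seq_len(nrow(segments))))
  lfp
}
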