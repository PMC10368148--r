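#' The analysis frequency band
#'
#' Default 25-59 Hz: the slow-gamma range evoked by kainate in hippocampal
#' slices, with the upper edge below 60 Hz to omit line noise.
#'
#' @param f_lo,f_hi band limits in Hz
#' @return numeric length-2 vector `c(f_lo, f_hi)`
#' @export
gbo_band <- function(f_lo = 25, f_hi = 59) {
  if (!(0 < f_lo && f_lo < f_hi))
    .gbo_error("band must satisfy 0 < f_lo < f_hi", "gbo_parameter_error")
  c(f_lo = f_lo, f_hi = f_hi)
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Solves Slepian's tridiagonal eigenproblem for the first `k` tapers. For
#' long windows (`n` above `max_exact`) the tapers are computed on a shorter
#' grid and spline-interpolated to length `n` (then renormalized), the usual
#' shortcut for multitaper analysis of long segments.
#'
#' @param n taper length in samples
#' @param nw time-half-bandwidth product
#' @param k number of tapers; must satisfy `k <= 2*nw - 1`
#' @param max_exact largest `n` solved exactly
#' @return `n x k` matrix, columns with unit energy
#' @export
dpss_tapers <- function(n, nw = 3, k = 5, max_exact = 2049) {
  if (k > 2 * nw - 1)
    .gbo_error("taper count K must satisfy K <= 2*NW - 1",
               "gbo_parameter_error")
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.gbo_cache[[key]])) return(.gbo_cache[[key]])
  if (n <= max_exact) {
    h <- .dpss_tridiag(as.integer(n), nw, as.integer(k))
  } else {
    base <- .dpss_tridiag(as.integer(max_exact), nw, as.integer(k))
    h <- apply(base, 2, function(col)
      spline(x = seq(0, 1, length.out = max_exact), y = col,
             xout = seq(0, 1, length.out = n))$y)
    h <- sweep(h, 2, sqrt(colSums(h^2)), "/")
  }
  .gbo_cache[[key]] <- h
  h
}

# tapered one-sided eigenspectra of a signal: returns complex matrix
# (n_freq x K) of taper FFTs; shared by PSD and coherence estimators
taper_ffts <- function(x, tapers) {
  n <- length(x)
  nf <- floor(n / 2) + 1L
  X <- stats::mvfft(tapers * x)
  X[seq_len(nf), , drop = FALSE]
}

onesided_scale <- function(n, fs) {
  nf <- floor(n / 2) + 1L
  sc <- rep(2 / fs, nf)
  sc[1] <- 1 / fs
  if (n %% 2 == 0) sc[nf] <- 1 / fs
  sc
}

#' Multitaper power spectral density
#'
#' Average of `k` Slepian eigenspectra; one-sided density normalized so the
#' integral over `[0, fs/2]` equals the signal variance (Parseval).
#'
#' @param x voltage series (microvolts)
#' @param fs sampling rate, Hz
#' @param nw time-half-bandwidth product (default 3)
#' @param k number of tapers (default 5)
#' @param demean subtract the mean before tapering (default `FALSE` so that
#'   a constant signal shows its power at 0 Hz)
#' @return list of class `gbo_psd` with `freqs_hz`, `power`
#'   (microvolt^2 / Hz), `fs`, `taper_params`
#' @export
multitaper_psd <- function(x, fs, nw = 3, k = 5, demean = FALSE) {
  if (length(x) < 2)
    .gbo_error("signal must have at least 2 samples", "gbo_parameter_error")
  if (demean) x <- x - mean(x)
  n <- length(x)
  h <- dpss_tapers(n, nw, k)
  X <- taper_ffts(x, h)
  pwr <- rowMeans(Mod(X)^2) * onesided_scale(n, fs)
  out <- list(freqs_hz = (seq_len(nrow(X)) - 1) * fs / n, power = pwr,
              fs = fs, taper_params = list(NW = nw, K = k))
  class(out) <- "gbo_psd"
  out
}

# mean of several PSDs on a shared grid
average_psd <- function(psds) {
  out <- psds[[1]]
  out$power <- rowMeans(vapply(psds, `[[`, numeric(length(out$power)),
                               "power"))
  out
}

#' Band power: integral of the spectral density over a band
#'
#' Trapezoidal integration of the density over `[f_lo, f_hi]`, with linear
#' interpolation at the exact band edges so that power is additive over
#' disjoint sub-bands sharing a grid.
#'
#' @param ps a `gbo_psd` (or list with `freqs_hz`, `power`)
#' @param band from [gbo_band()]
#' @return band power, microvolt^2
#' @export
band_power <- function(ps, band = gbo_band()) {
  f <- ps$freqs_hz; p <- ps$power
  if (band[1] < f[1] || band[2] > f[length(f)])
    .gbo_error("band outside the spectrum range", "gbo_parameter_error")
  inside <- f > band[1] & f < band[2]
  fg <- c(band[1], f[inside], band[2])
  pg <- c(approx(f, p, xout = band[1])$y, p[inside],
          approx(f, p, xout = band[2])$y)
  sum(diff(fg) * (head(pg, -1) + tail(pg, -1)) / 2)
}

#' Sliding-window band power
#'
#' Multitaper PSD + band power in consecutive windows for every channel;
#' the substrate for onset/offset kinetics and power-envelope correlation.
#'
#' @param lfp a `gbo_lfp`/`gbo_recording`
#' @param band analysis band
#' @param window_s window length (default 2 s)
#' @param step_s window step (default 1 s)
#' @param nw,k multitaper parameters
#' @return list of class `gbo_bandpower` with `times_s` (window centers),
#'   `power` (channels x windows), `band`, `window_s`, `step_s`, `layout`,
#'   `epochs`, `slice_id`
#' @export
sliding_band_power <- function(lfp, band = gbo_band(), window_s = 2,
                               step_s = 1, nw = 3, k = 5) {
  fs <- lfp$fs_hz
  n <- ncol(lfp$data)
  wlen <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  if (wlen > n)
    .gbo_error("window longer than the record", "gbo_parameter_error")
  starts <- seq.int(1L, n - wlen + 1L, by = step)
  h <- dpss_tapers(wlen, nw, k)
  sc <- onesided_scale(wlen, fs)
  nf <- floor(wlen / 2) + 1L
  freqs <- (seq_len(nf) - 1) * fs / wlen
  nch <- nrow(lfp$data)
  pow <- matrix(0, nch, length(starts))
  for (w in seq_along(starts)) {
    seg <- lfp$data[, starts[w]:(starts[w] + wlen - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    acc <- matrix(0, nf, nch)
    for (j in seq_len(k)) {
      X <- stats::mvfft(t(seg) * h[, j])
      acc <- acc + Mod(X[seq_len(nf), , drop = FALSE])^2
    }
    dens <- acc / k * sc
    for (ch in seq_len(nch))
      pow[ch, w] <- band_power(list(freqs_hz = freqs, power = dens[, ch]),
                               band)
  }
  out <- list(times_s = (starts - 1 + wlen / 2) / fs, power = pow,
              band = band, window_s = window_s, step_s = step_s,
              layout = lfp$layout, epochs = lfp$epochs,
              slice_id = lfp$slice_id)
  class(out) <- "gbo_bandpower"
  out
}

#' Morlet wavelet spectrogram
#'
#' Convolves one channel with complex Morlet wavelets
#' `w(t, f0) = A exp(-t^2 / (2 sigma_t^2)) exp(2 pi i f0 t)` where, for
#' wavelet width `m`, `sigma_f = f0 / m`, `sigma_t = 1 / (2 pi sigma_f)` and
#' `A = (sigma_t sqrt(pi))^(-1/2)`. Power is the squared magnitude of the
#' convolution; samples within `3 sigma_t` of the record ends are set `NA`
#' (edge effects).
#'
#' @param x one channel, microvolts
#' @param fs sampling rate
#' @param freqs frequency grid (default 1-100 Hz in 0.5 Hz steps)
#' @param m wavelet width (default 25)
#' @return list of class `gbo_spectrogram` with `times_s`, `freqs_hz`,
#'   `power` (freq x time)
#' @export
morlet_spectrogram <- function(x, fs, freqs = seq(1, 100, by = 0.5), m = 25) {
  n <- length(x)
  if (any(freqs <= 0 | freqs >= fs / 2))
    .gbo_error("wavelet frequencies must lie in (0, Nyquist)",
               "gbo_parameter_error")
  keep <- vapply(freqs, function(f0) {
    sig_t <- m / (2 * pi * f0)
    3 * sig_t <= n / fs / 2
  }, logical(1))
  if (!all(keep)) {
    warning(sprintf("dropping %d frequencies whose wavelet exceeds half the record",
                    sum(!keep)))
    freqs <- freqs[keep]
  }
  pow <- matrix(NA_real_, length(freqs), n)
  xf <- fft(c(x, rep(0, n)))        # zero-padded for linear convolution
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sig_f <- f0 / m
    sig_t <- 1 / (2 * pi * sig_f)
    half <- min(ceiling(4 * sig_t * fs), n - 1)
    tt <- (-half:half) / fs
    w <- (sig_t * sqrt(pi))^(-1 / 2) *
      exp(-tt^2 / (2 * sig_t^2)) * exp(2i * pi * f0 * tt)
    wpad <- complex(length.out = 2 * n)
    wpad[seq_along(tt)] <- w
    conv <- fft(xf * fft(wpad), inverse = TRUE) / (2 * n)
    vals <- conv[(half + 1):(half + n)] / fs      # centered, * dt
    p <- Mod(vals)^2
    edge <- ceiling(3 * sig_t * fs)
    if (edge >= 1) {
      p[seq_len(min(edge, n))] <- NA_real_
      p[seq.int(max(1, n - edge + 1), n)] <- NA_real_
    }
    pow[i, ] <- p
  }
  out <- list(times_s = (seq_len(n) - 1) / fs, freqs_hz = freqs, power = pow,
              wavelet_width = m)
  class(out) <- "gbo_spectrogram"
  out
}

#' Peak frequency, half-max bandwidth and Q factor
#'
#' `f0` is the frequency of maximal density inside `search_band` (ties broken
#' toward lower frequency); `B` is the distance between the outermost
#' half-maximum crossings flanking `f0` (linear interpolation between bins);
#' `Q = f0 / B`. Q above 0.5 is the conventional rhythmicity criterion for
#' kainate-evoked oscillations.
#'
#' @param ps a `gbo_psd`
#' @param search_band band searched for the peak. The default starts at 5 Hz
#'   (rather than the 25 Hz analysis-band edge) because CA3 oscillation peaks
#'   can fall just below 25 Hz.
#' @return list of class `gbo_peak` with `f0`, `B`, `Q`
#' @export
peak_and_q <- function(ps, search_band = gbo_band(5, 59)) {
  f <- ps$freqs_hz; p <- ps$power
  if (search_band[1] < f[1] || search_band[2] > f[length(f)])
    .gbo_error("spectrum does not cover the search band",
               "gbo_parameter_error")
  in_band <- which(f >= search_band[1] & f <= search_band[2])
  ipk <- in_band[which.max(p[in_band])]   # which.max takes first = lowest f
  pmax_ <- p[ipk]
  half <- pmax_ / 2
  crossing <- function(i, j) {
    # linear interpolation of the half-max crossing between bins i and j
    f[i] + (half - p[i]) * (f[j] - f[i]) / (p[j] - p[i])
  }
  below <- p < half
  np <- length(p)
  # upward crossings left of the peak / downward crossings right of it
  left <- if (ipk > 1)
    which(below[seq_len(ipk - 1)] & !below[seq_len(ipk - 1) + 1]) else integer()
  right <- if (ipk < np)
    which(below[seq.int(ipk + 1, np)] &
          !below[seq.int(ipk, np - 1)]) + ipk else integer()
  if (length(left) == 0 || length(right) == 0)
    .gbo_error("no half-maximum crossing flanking the peak; Q undefined",
               "gbo_q_undefined")
  il <- min(left)                    # outermost crossing on the left
  fl <- crossing(il, il + 1)
  ir <- max(right)                   # outermost crossing on the right
  fr <- crossing(ir, ir - 1)
  B <- fr - fl
  out <- list(f0 = f[ipk], B = B, Q = f[ipk] / B)
  class(out) <- "gbo_peak"
  out
}

#' Mean multitaper PSD over a time window of one channel
#'
#' Welch-style average of 2 s multitaper spectra, the standard way this
#' package estimates the stationary spectrum of an epoch (e.g. the last
#' 10 min of drug application for Q-factor reporting).
#'
#' @param lfp a `gbo_lfp`
#' @param channel electrode id (0-based)
#' @param samples sample index vector, e.g. from [epoch_samples()]
#' @param window_s,nw,k spectral parameters
#' @return a `gbo_psd`
#' @export
epoch_psd <- function(lfp, channel, samples, window_s = 2, nw = 3, k = 5) {
  x <- lfp$data[channel + 1L, samples]
  fs <- lfp$fs_hz
  wlen <- round(window_s * fs)
  starts <- seq.int(1L, length(x) - wlen + 1L, by = wlen)
  psds <- lapply(starts, function(s0) {
    seg <- x[s0:(s0 + wlen - 1L)]
    multitaper_psd(seg - mean(seg), fs, nw, k)
  })
  average_psd(psds)
}
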