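# tapered segment FFTs for a channel: complex matrix (n_freq x nseg*K),
# segments demeaned; shared by the coherence estimators
segment_ffts <- function(x, fs, window_s, nw, k) {
  wlen <- round(window_s * fs)
  if (length(x) < wlen)
    .gbo_error("signal shorter than one window", "gbo_parameter_error")
  starts <- seq.int(1L, length(x) - wlen + 1L, by = wlen)
  h <- dpss_tapers(wlen, nw, k)
  nf <- floor(wlen / 2) + 1L
  out <- matrix(0i, nf, length(starts) * k)
  col <- 1L
  for (s0 in starts) {
    seg <- x[s0:(s0 + wlen - 1L)]
    seg <- seg - mean(seg)
    X <- stats::mvfft(h * seg)
    out[, col:(col + k - 1L)] <- X[seq_len(nf), ]
    col <- col + k
  }
  list(F = out, freqs = (seq_len(nf) - 1) * fs / wlen)
}

#' Multitaper magnitude coherence spectrum
#'
#' Auto- and cross-spectra are averaged over Slepian tapers and
#' non-overlapping windows; coherence is `|S_xy| / sqrt(S_x * S_y)`, clipped
#' to `[0, 1]` against rounding. With `type = "real"` the normalized real
#' part of the cross-spectrum (the zero-lag component) is returned instead.
#'
#' @param x,y equal-length voltage series
#' @param fs sampling rate
#' @param nw,k multitaper parameters
#' @param window_s averaging window length (default 2 s)
#' @param type `"magnitude"` (default) or `"real"`
#' @return list of class `gbo_coherence` with `freqs_hz`, `coherence`
#' @export
multitaper_coherence <- function(x, y, fs, nw = 3, k = 5, window_s = 2,
                                 type = c("magnitude", "real")) {
  type <- match.arg(type)
  if (length(x) != length(y))
    .gbo_error("signals must have equal length", "gbo_parameter_error")
  Fx <- segment_ffts(x, fs, window_s, nw, k)
  Fy <- segment_ffts(y, fs, window_s, nw, k)
  Sx <- rowMeans(Mod(Fx$F)^2)
  Sy <- rowMeans(Mod(Fy$F)^2)
  Sxy <- rowMeans(Fx$F * Conj(Fy$F))
  num <- if (type == "magnitude") Mod(Sxy) else Re(Sxy)
  coh <- num / sqrt(Sx * Sy)
  coh <- pmin(pmax(coh, if (type == "magnitude") 0 else -1), 1)
  structure(list(freqs_hz = Fx$freqs, coherence = coh, type = type,
                 n_segments = ncol(Fx$F) / k, taper_params = list(NW = nw,
                                                                  K = k)),
            class = "gbo_coherence")
}

#' Band-averaged coherence
#'
#' Mean of the coherence spectrum over the analysis band (grid points with
#' `f_lo <= f <= f_hi`).
#'
#' @param cs a `gbo_coherence`
#' @param band from [gbo_band()]
#' @return scalar in `[0, 1]`
#' @export
band_coherence <- function(cs, band = gbo_band()) {
  f <- cs$freqs_hz
  if (band[1] < f[1] || band[2] > f[length(f)])
    .gbo_error("band outside the coherence spectrum range",
               "gbo_parameter_error")
  mean(cs$coherence[f >= band[1] & f <= band[2]])
}

region_pair_label <- function(r1, r2) {
  if (r1 == r2) paste0("within_", r1) else "between_CA1_CA3"
}

#' Pairwise band-coherence table over all labeled electrode pairs
#'
#' Computes band coherence for every unordered pair of CA1/CA3 electrodes
#' (`elec1 < elec2`, reference and unlabeled electrodes excluded) in a
#' vehicle window and a drug window, plus the drug/vehicle fold change —
#' one row per pair, the substrate for the mixed-effects models.
#'
#' @param lfp a `gbo_lfp`
#' @param vehicle_window,drug_window numeric `[t0, t1)` windows in seconds;
#'   defaults: the last `last_s` seconds of the vehicle and drug epochs
#' @param last_s default condition-window length, seconds (300 at full
#'   scale, shrunk proportionally for short epochs)
#' @param band analysis band
#' @param nw,k,window_s multitaper parameters
#' @return data.frame with columns slice_id, elec1, elec2, region_pair,
#'   coh_vehicle, coh_drug, fold_change
#' @export
pairwise_table <- function(lfp, vehicle_window = NULL, drug_window = NULL,
                           last_s = 300, band = gbo_band(),
                           nw = 3, k = 5, window_s = 2) {
  lay <- lfp$layout
  elecs <- recording_electrodes(lay)
  if (length(elecs) < 2)
    .gbo_error("need at least 2 labeled non-reference electrodes",
               "gbo_parameter_error")
  for (r in c("CA1", "CA3"))
    if (sum(lay$region[match(elecs, lay$electrode_id)] == r) < 1)
      warning(sprintf("region %s has no electrodes; its pairs are absent", r))
  win <- function(label, given) {
    if (!is.null(given)) return(given)
    ep <- lfp$epochs[lfp$epochs$label == label, ]
    w <- min(last_s, ep$t_end_s - ep$t_start_s)
    c(ep$t_end_s - w, ep$t_end_s)
  }
  vw <- win("vehicle", vehicle_window)
  dw <- win("kainate", drug_window)
  fs <- lfp$fs_hz
  idx <- function(w) seq.int(floor(w[1] * fs) + 1L,
                             min(floor(w[2] * fs), ncol(lfp$data)))
  fband <- NULL
  # precompute tapered segment FFTs per channel and condition, band bins only
  getF <- function(samples) {
    Fs <- vector("list", length(elecs))
    for (i in seq_along(elecs)) {
      sf <- segment_ffts(lfp$data[elecs[i] + 1L, samples], fs, window_s,
                         nw, k)
      if (is.null(fband)) fband <<- which(sf$freqs >= band[1] &
                                            sf$freqs <= band[2])
      Fs[[i]] <- sf$F[fband, , drop = FALSE]
    }
    Fs
  }
  Fv <- getF(idx(vw)); Fd <- getF(idx(dw))
  reg <- as.character(lay$region[match(elecs, lay$electrode_id)])
  pairs <- utils::combn(seq_along(elecs), 2)
  n_pairs <- ncol(pairs)
  bc <- function(Fi, Fj) {
    Sx <- rowMeans(Mod(Fi)^2); Sy <- rowMeans(Mod(Fj)^2)
    Sxy <- rowMeans(Fi * Conj(Fj))
    mean(pmin(Mod(Sxy) / sqrt(Sx * Sy), 1))
  }
  out <- data.frame(
    slice_id = rep(lfp$slice_id, n_pairs),
    elec1 = elecs[pairs[1, ]], elec2 = elecs[pairs[2, ]],
    region_pair = vapply(seq_len(n_pairs), function(q)
      region_pair_label(reg[pairs[1, q]], reg[pairs[2, q]]), character(1)),
    coh_vehicle = vapply(seq_len(n_pairs), function(q)
      bc(Fv[[pairs[1, q]]], Fv[[pairs[2, q]]]), numeric(1)),
    coh_drug = vapply(seq_len(n_pairs), function(q)
      bc(Fd[[pairs[1, q]]], Fd[[pairs[2, q]]]), numeric(1)),
    stringsAsFactors = FALSE)
  out$fold_change <- out$coh_drug / out$coh_vehicle
  out
}

#' Pearson correlation map of band-power envelopes
#'
#' Correlates the band-power time courses of every electrode pair over a
#' time window; the "power correlation" companion of spectral coherence.
#' Zero-variance channels yield `NA` rows/columns (flagged by a warning).
#'
#' @param bp a `gbo_bandpower`
#' @param window optional `[t0, t1)` restriction in seconds
#' @return symmetric channels x channels correlation matrix, unit diagonal
#' @export
power_correlation_map <- function(bp, window = NULL) {
  keep <- rep(TRUE, length(bp$times_s))
  if (!is.null(window))
    keep <- bp$times_s >= window[1] & bp$times_s < window[2]
  m <- t(bp$power[, keep, drop = FALSE])
  if (nrow(m) < 3)
    .gbo_error("need at least 3 time points", "gbo_parameter_error")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    warning("zero-variance channel(s); correlations flagged NA")
  r <- suppressWarnings(cor(m))
  diag(r) <- 1
  r
}

#' Thresholded coherence graph of one slice and condition
#'
#' Nodes are electrodes (with grid coordinates, region and band power as
#' attributes, node `size` proportional to band power); edges connect pairs
#' whose band coherence is at or above `threshold` (inclusive, default
#' 0.45).
#'
#' @param records a [pairwise_table()] data.frame for one slice
#' @param layout the electrode layout
#' @param band_power_by_elec named numeric: band power per electrode id
#' @param condition `"drug"` or `"vehicle"` (chooses the coherence column)
#' @param threshold edge threshold (default 0.45)
#' @return an `igraph` graph
#' @export
build_graph <- function(records, layout, band_power_by_elec = NULL,
                        condition = c("drug", "vehicle"), threshold = 0.45) {
  condition <- match.arg(condition)
  col <- paste0("coh_", condition)
  elecs <- sort(unique(c(records$elec1, records$elec2)))
  li <- match(elecs, layout$electrode_id)
  bp <- if (is.null(band_power_by_elec)) rep(1, length(elecs)) else
    as.numeric(band_power_by_elec[as.character(elecs)])
  nodes <- data.frame(name = as.character(elecs),
                      x_um = layout$x_um[li], y_um = layout$y_um[li],
                      region = as.character(layout$region[li]),
                      band_power = bp,
                      size = bp / max(bp, na.rm = TRUE))
  keep <- records[[col]] >= threshold
  edges <- data.frame(from = as.character(records$elec1[keep]),
                      to = as.character(records$elec2[keep]),
                      weight = records[[col]][keep])
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a coherence graph
#'
#' @param g graph from [build_graph()]
#' @param path_edges CSV path for the edge list (optional)
#' @param path_graphml GraphML path (optional)
#' @return invisibly, the edge-list data.frame
#' @export
export_graph <- function(g, path_edges = NULL, path_graphml = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (!is.null(path_edges)) write.csv(el, path_edges, row.names = FALSE)
  if (!is.null(path_graphml)) igraph::write_graph(g, path_graphml,
                                                  format = "graphml")
  invisible(el)
}
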