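# shared fixtures, built in code at test time

# a minimal LFP-like object with arbitrary data (for estimator-level tests)
fake_lfp <- function(data, fs = 1000, layout = make_layout(),
                     duration_split = c(0.4, 0.4, 0.2), slice_id = "fx") {
  n <- ncol(data)
  edges <- cumsum(c(0, round(duration_split / sum(duration_split) * n))) / fs
  epochs <- data.frame(label = c("vehicle", "kainate",
                                 "kainate_bicuculline"),
                       t_start_s = edges[1:3], t_end_s = edges[2:4])
  structure(list(data = data, fs_hz = fs, layout = layout, epochs = epochs,
                 slice_id = slice_id, ground_truth = NULL,
                 provenance = list(decimation_factor = 1L)),
            class = c("gbo_lfp", "gbo_recording"))
}

# small desk-scale simulator config used across tests
test_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, fs_hz = 2000,
             duration_s = c(vehicle = 30, drug = 120, antagonist = 30),
             onset = list(a = 3, b = 0.5), ...)
}

sine <- function(f, dur, fs, amp = 1) amp * sin(2 * pi * f * seq(0, dur, by = 1 / fs))
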