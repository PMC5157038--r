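# small deterministic fixtures shared across test files

make_test_recording <- function(fs = 1000, dur = 4, triggers = c(0.5, 1, 1.5),
                                seed = 42) {
  withr::with_seed(seed, {
    n <- dur * fs
    t <- (seq_len(n) - 1) / fs
    data <- cbind(C3 = 50 * sin(2 * pi * 10 * t) + rnorm(n),
                  C4 = 30 * cos(2 * pi * 12 * t) + rnorm(n),
                  EOG = rnorm(n, sd = 10))
    recording(data, fs = fs, triggers = triggers,
              meta = list(subject = "T01", hand = "right",
                          hand_status = "healthy", imi = 0.5))
  })
}

# toy envelope_signal without running the filter chain
toy_envelope <- function(values, fs, channel = "C3", band = "alpha") {
  structure(list(values = values, fs = fs, channel = channel, band = band,
                 band_edges = c(8, 14), method = "rectify_smooth"),
            class = "envelope_signal")
}

# toy averaged response on a given relative time axis
toy_response <- function(time, values, block = 1) {
  structure(list(time = time, values = values, block_size = 60,
                 block = block, band = "alpha", channel = "C3",
                 n_discarded = 0),
            class = "event_related_response")
}

# brute-force retention oracle: independent re-derivation of the rules
retention_oracle <- function(imd, eog_peak, imi, dev_thr = 0.5,
                             eog_thr = 300) {
  mapply(function(d, e) {
    if (is.na(d)) return("rejected_first")
    if (e >= eog_thr) return("rejected_artifact")
    if (abs(d - imi) >= dev_thr) return("rejected_timing")
    "retained"
  }, imd, eog_peak)
}
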