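# Build an envelope object directly from given frame values (one or more
# channels), for segmentation tests that need exact control over frames.
make_env <- function(values, fs_env = 16, normalized = TRUE) {
  values <- tibble::as_tibble(values)
  values <- dplyr::bind_cols(
    tibble::tibble(time = (seq_len(nrow(values)) - 1) / fs_env), values)
  gaitsemg:::new_envelope(values, fs_env = fs_env, window = 1 / fs_env,
                          overlap = 0, normalized = normalized,
                          src = tibble::tibble())
}

# A recording whose envelope shows rectangular bursts at known frame times:
# low-level noise floor with high-amplitude noise bursts.
burst_recording <- function(burst_starts, burst_len = 0.5, duration = 10,
                            fs = 1000, floor_amp = 0.1, burst_amp = 1,
                            seed = 42) {
  set.seed(seed)
  n <- duration * fs
  t <- (seq_len(n) - 1) / fs
  amp <- rep(floor_amp, n)
  for (b in burst_starts) amp[t >= b & t < b + burst_len] <- burst_amp
  emg_recording(list(right_TA = amp * rnorm(n)), fs = fs)
}
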