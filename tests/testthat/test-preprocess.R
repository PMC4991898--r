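tone_recording <- function(freq, fs = 2000, duration = 4) {
  t <- (seq_len(duration * fs) - 1) / fs
  emg_recording(list(right_TA = sin(2 * pi * freq * t)), fs = fs)
}
rms_of <- function(x) sqrt(mean(x^2))

test_that("the filter notches 50 Hz, rejects sub-band and passes in-band tones", {
  out50 <- bandpass_notch(tone_recording(50))
  expect_lt(rms_of(out50$right_TA), 0.05 * rms_of(tone_recording(50)$right_TA))
  out5 <- bandpass_notch(tone_recording(5))
  expect_lt(rms_of(out5$right_TA), 0.20 * rms_of(tone_recording(5)$right_TA))
  out100 <- bandpass_notch(tone_recording(100))
  expect_equal(rms_of(out100$right_TA),
               rms_of(tone_recording(100)$right_TA), tolerance = 0.05)
})

test_that("impossible bands and too-short signals are rejected", {
  rec <- tone_recording(100)
  expect_error(bandpass_notch(rec, low = 10, high = 1100), "fs/2")
  expect_error(bandpass_notch(rec, low = 0, high = 500), "fs/2")
  tiny <- emg_recording(list(right_TA = rnorm(10)), fs = 2000)
  expect_error(bandpass_notch(tiny), "too short")
})

test_that("RMS envelope reproduces known window statistics", {
  const <- emg_recording(list(right_TA = rep(3, 1000)), fs = 1000)
  expect_true(all(abs(rms_envelope(const)$right_TA - 3) < 1e-12))
  alt <- emg_recording(list(right_TA = rep(c(1, -1), 500)), fs = 1000)
  expect_true(all(abs(rms_envelope(alt, window = 0.05)$right_TA - 1) < 1e-12))
  zero <- emg_recording(list(right_TA = rep(0, 1000)), fs = 1000)
  expect_true(all(rms_envelope(zero)$right_TA == 0))
})

test_that("RMS envelope is scale-equivariant", {
  set.seed(11)
  x <- rnorm(2000)
  e1 <- rms_envelope(emg_recording(list(left_MG = x), fs = 1000))
  e2 <- rms_envelope(emg_recording(list(left_MG = -2.5 * x), fs = 1000))
  expect_equal(e2$left_MG, 2.5 * e1$left_MG, tolerance = 1e-12)
})

test_that("degenerate envelope windows are rejected", {
  rec <- emg_recording(list(right_TA = rnorm(100)), fs = 1000)
  expect_error(rms_envelope(rec, window = 0.5), "longer than the signal")
  expect_error(rms_envelope(rec, window = 0.001), "at least 2 samples")
  expect_error(rms_envelope(rec, overlap = 1), "overlap")
})

test_that("MVC extraction smooths single-frame spikes", {
  fs <- 1000
  amp <- rep(1, 10 * fs)
  amp[5000:5125] <- 100                 # one RMS window's worth of spike
  set.seed(3)
  rec <- emg_recording(list(right_TA = amp * rnorm(10 * fs)), fs = fs)
  env <- rms_envelope(rec)
  ref <- extract_mvc(env)
  expect_lt(ref$mvc, max(env$right_TA) / 2)   # closer to base than spike
  expect_gt(ref$mvc, 1)
  const <- rms_envelope(emg_recording(list(left_SOL = rep(2, 4000)), fs = fs))
  expect_equal(extract_mvc(const)$mvc, 2, tolerance = 1e-12)
  zero <- rms_envelope(emg_recording(list(left_SOL = rep(0, 4000)), fs = fs))
  expect_error(extract_mvc(zero), "zero MVC")
})

test_that("%MVC normalization rescales, guards its inputs, and is not repeatable", {
  env <- rms_envelope(emg_recording(list(right_TA = rep(0.5, 2000)), fs = 1000))
  ref <- tibble::tibble(side = "right", muscle = "TA", mvc = 2)
  norm <- mvc_normalize(env, ref)
  expect_true(all(abs(norm$right_TA - 25) < 1e-12))
  ref_same <- tibble::tibble(side = "right", muscle = "TA", mvc = 0.5)
  expect_true(all(abs(mvc_normalize(env, ref_same)$right_TA - 100) < 1e-12))
  expect_error(mvc_normalize(env, tibble::tibble(side = "right",
                                                 muscle = "TA", mvc = 0)),
               "positive")
  expect_error(mvc_normalize(env, tibble::tibble(side = "left",
                                                 muscle = "TA", mvc = 1)),
               "No MVC reference")
  expect_error(mvc_normalize(norm, ref), "already normalized")
  expect_true(all(norm$right_TA >= 0))
})
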