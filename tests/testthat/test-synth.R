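test_that("identical parameters give bit-identical recordings", {
  p <- synth_params(duration = 2, speed = 3, seed = 5)
  expect_identical(synth_gait_emg(p), synth_gait_emg(p))
  expect_identical(synth_static_emg(p), synth_static_emg(p))
  expect_identical(synth_mvc_trial("TA", seed = 5), synth_mvc_trial("TA", seed = 5))
})

test_that("ground truth counts one onset per cycle", {
  p <- synth_params(duration = 10 * 0.8, speed = 3, muscles = "TA", seed = 1)
  gt <- synth_ground_truth(synth_gait_emg(p))
  expect_length(gt$onset_times, 10)
  expect_equal(gt$n_cycles, 10)
  expect_equal(diff(gt$onset_times), rep(p$cycle_duration, 9))
})

test_that("TA is more active in its swing window than in stance", {
  p <- synth_params(duration = 10, speed = 3, muscles = "TA", seed = 3)
  rec <- synth_gait_emg(p)
  env <- rms_envelope(rec)
  phase <- (env$time %% p$cycle_duration) / p$cycle_duration
  expect_gt(mean(env$right_TA[phase >= 0.6]),
            2 * mean(env$right_TA[phase < 0.6]))
})

test_that("standing envelopes reflect injected asymmetry gains", {
  p <- synth_params(duration = 60, muscles = "SOL", seed = 9,
                    asymmetry = c(left_SOL = 2))
  env <- rms_envelope(synth_static_emg(p))
  ratio <- mean(env$left_SOL) / mean(env$right_SOL)
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("equal gains give converging left/right envelope means", {
  p <- synth_params(duration = 30, speed = 3, muscles = "MG", seed = 13)
  env <- rms_envelope(synth_gait_emg(p))
  expect_equal(mean(env$left_MG) / mean(env$right_MG), 1, tolerance = 0.05)
})

test_that("zero baseline gives an all-zero standing signal", {
  p <- synth_params(duration = 1, muscles = "TA", baseline_level = 0, seed = 2)
  rec <- synth_static_emg(p)
  expect_true(all(rec$left_TA == 0) && all(rec$right_TA == 0))
})

test_that("MVC trials dominate sub-maximal standing activity", {
  p <- synth_params(duration = 5, muscles = "TA", seed = 4,
                    baseline_level = 0.2)
  env_static <- rms_envelope(synth_static_emg(p))
  env_mvc <- rms_envelope(synth_mvc_trial("TA", mvc_amplitude = 0.5,
                                          fs = p$fs, seed = 4))
  expect_gt(max(env_mvc$right_TA), max(env_static$right_TA))
})

test_that("a zero-amplitude MVC trial makes normalization impossible", {
  trial <- synth_mvc_trial("TA", mvc_amplitude = 0, fs = 1000, seed = 1)
  expect_true(all(trial$left_TA == 0))
  expect_error(extract_mvc(rms_envelope(trial)), "zero MVC")
})

test_that("carrier power is confined to the noise band", {
  p <- synth_params(duration = 10, muscles = "TA", seed = 2)
  x <- synth_gait_emg(p)$right_TA
  pw <- Mod(fft(x))^2
  freq <- (seq_along(x) - 1) * p$fs / length(x)
  freq <- pmin(freq, p$fs - freq)
  out_frac <- sum(pw[freq < 10 | freq > 500]) / sum(pw)
  expect_lt(out_frac, 0.01)
})

test_that("invalid generator parameters are rejected", {
  expect_error(synth_params(duration = 0), "positive")
  expect_error(synth_params(noise_band = c(10, 1200)), "fs/2")
  expect_error(synth_params(noise_band = c(0, 500)), "fs/2")
  expect_error(synth_params(asymmetry = c(left_EAR = 2)), "Unknown")
  expect_error(synth_mvc_trial("TA", duration = 0.5), "1 s")
})
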