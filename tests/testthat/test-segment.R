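test_that("a constant envelope yields no onsets", {
  env <- make_env(list(right_TA = rep(5, 100)))
  expect_identical(detect_onsets(env), integer(0))
})

test_that("rectangular bursts are detected at their true frames", {
  starts <- c(1, 2.5, 4, 5.5, 7, 8.5)
  rec <- burst_recording(starts, burst_len = 0.5, duration = 10, fs = 1000)
  env <- rms_envelope(rec, window = 0.1, overlap = 0)   # 10 frames/s
  on <- detect_onsets(env, "right_TA")
  true_frames <- starts * 10 + 1
  expect_length(on, length(starts))
  expect_true(all(abs(on - true_frames) <= 1))
})

test_that("a long refractory suppresses every second burst", {
  starts <- seq(1, 9, by = 1)
  rec <- burst_recording(starts, burst_len = 0.4, duration = 11, fs = 1000)
  env <- rms_envelope(rec, window = 0.1, overlap = 0)
  on <- detect_onsets(env, "right_TA", min_separation = 1.5)
  expect_length(on, ceiling(length(starts) / 2))
  expect_true(all(diff(on) >= 15))
})

test_that("onset indices are invariant to uniform envelope scaling", {
  rec <- burst_recording(c(1, 3, 5), duration = 7, fs = 1000)
  env <- rms_envelope(rec, window = 0.1, overlap = 0)
  env10 <- env
  env10$right_TA <- env10$right_TA * 10
  expect_identical(detect_onsets(env, "right_TA"),
                   detect_onsets(env10, "right_TA"))
})

test_that("onsets cut half-open contiguous cycles", {
  cyc <- segment_cycles(c(100, 600, 1100))
  expect_equal(cyc$start, c(100, 600))
  expect_equal(cyc$end, c(600, 1100))
  expect_equal(cyc$cycle, 1:2)
  expect_warning(one <- segment_cycles(500), "Fewer than two")
  expect_equal(nrow(one), 0)
  expect_error(segment_cycles(c(5, 5)), "strictly increasing")
  expect_error(segment_cycles(c(10, 8)), "strictly increasing")
})

test_that("time normalization interpolates linearly on the phase grid", {
  n_f <- 201
  env <- make_env(list(right_TA = seq(0, 1, length.out = n_f)))
  cyc <- segment_cycles(c(1, n_f))
  curve <- suppressWarnings(time_normalize(env, cyc))
  expect_equal(nrow(curve), 100)
  expect_equal(curve$phase, (0:99) / 100)
  expect_lt(max(abs(curve$value - (0:99) / 100)), 1 / (n_f - 1))

  env_c <- make_env(list(left_SOL = rep(7, 50)))
  curve_c <- time_normalize(env_c, segment_cycles(c(1, 50)))
  expect_true(all(curve_c$value == 7))
})

test_that("a 100-frame cycle reproduces its frames verbatim", {
  set.seed(21)
  vals <- runif(120)
  env <- make_env(list(right_MG = vals))
  curve <- time_normalize(env, segment_cycles(c(11, 111)))
  expect_equal(curve$value, vals[11:110])
})

test_that("degenerate cycles are rejected", {
  env <- make_env(list(right_TA = rnorm(50)))
  cyc <- tibble::tibble(cycle = 1L, start = 10L, end = 11L)
  expect_error(time_normalize(env, cyc), "Degenerate")
})

test_that("ensemble averaging matches a direct two-pass computation", {
  set.seed(31)
  n_curves <- 50
  curves <- dplyr::bind_rows(lapply(seq_len(n_curves), function(i) {
    tibble::tibble(cycle = i, side = "left", muscle = "LG",
                   phase = (0:99) / 100, value = runif(100))
  }))
  ens <- ensemble_average(curves)
  expect_equal(nrow(ens), 100)
  expect_true(all(ens$n_cycles == n_curves))
  # independent two-pass oracle
  mat <- matrix(curves$value, nrow = 100)   # phases x cycles
  expect_equal(ens$mean, rowMeans(mat))
  expect_equal(ens$sd, apply(mat, 1, function(v)
    sqrt(sum((v - mean(v))^2) / length(v))))
})

test_that("ensembles of identical curves have zero SD and the curve as mean", {
  base <- tibble::tibble(side = "right", muscle = "TA",
                         phase = (0:99) / 100, value = sin((0:99) / 10))
  curves <- dplyr::bind_rows(lapply(1:5, function(i)
    dplyr::mutate(base, cycle = i)))
  ens <- ensemble_average(curves)
  expect_equal(ens$mean, base$value)
  expect_true(all(ens$sd < 1e-12))

  a <- dplyr::mutate(base, cycle = 1)
  b <- dplyr::mutate(base, cycle = 2, value = base$value + 1)
  ens2 <- ensemble_average(dplyr::bind_rows(a, b))
  expect_equal(ens2$mean, base$value + 0.5)
  expect_error(ensemble_average(a[0, ]), "No cycle curves")
})

test_that("phase annotation splits stance and swing as configured", {
  curve <- tibble::tibble(phase = (0:99) / 100, value = 0)
  lab <- phase_annotation(curve)
  expect_equal(sum(lab$phase_label == "stance"), 60)
  expect_equal(sum(lab$phase_label == "swing"), 40)
  lab50 <- phase_annotation(curve, stance_fraction = 0.5)
  expect_equal(sum(lab50$phase_label == "stance"), 50)
  expect_error(phase_annotation(curve, stance_fraction = 1.2), "inside")
  expect_error(phase_annotation(curve, stance_fraction = 0), "inside")
})

test_that("both limbs are cut on the right-TA cycle clock", {
  p <- synth_params(duration = 8, speed = 3, seed = 17)
  rec <- synth_gait_emg(p)
  env <- mvc_normalize(rms_envelope(rec), synth_mvc_reference(p))
  cyc <- segment_cycles(detect_onsets(env, "right_TA"))
  curves <- time_normalize(env, cyc)
  counts <- dplyr::count(curves, .data$side, .data$muscle)
  expect_equal(length(unique(counts$n)), 1)   # same cycles for all channels
  expect_setequal(unique(paste(curves$side, curves$muscle)),
                  paste(rep(c("left", "right"), 4),
                        rep(c("TA", "SOL", "LG", "MG"), each = 2)))
})
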