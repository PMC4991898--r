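#' Phase-domain muscle activation templates
#'
#' A template is a smooth, periodic, non-negative activation profile
#' \eqn{e(\phi)} over gait phase \eqn{\phi \in [0, 1)}, built as a sum of
#' wrapped Gaussian bumps. Phase 0 is the onset of right tibialis anterior
#' activity, the event that defines the start of a gait cycle here.
#'
#' The defaults encode the qualitative timing of the four muscles during
#' walking: TA carries its main burst late in the cycle (swing, centred at
#' phase 0.78) plus a small burst at phase 0 where the swing-to-stance
#' transition produces simultaneous activity of all four muscles; SOL is
#' broadly active through stance; LG and MG fire in late stance (centred at
#' phase 0.45).
#'
#' @param center Bump centres, phases in `[0, 1)`.
#' @param width Bump widths (Gaussian SD in phase units, > 0).
#' @param amplitude Relative bump amplitudes (>= 0).
#' @return `activation_template()` returns a tibble with columns `center`,
#'   `width`, `amplitude`; `default_activation_templates()` a named list of
#'   such tibbles, one per muscle.
#' @export
#' @examples
#' tpl <- default_activation_templates()
#' eval_template(tpl$TA, c(0, 0.25, 0.78))
activation_template <- function(center, width, amplitude) {
  stopifnot(length(center) == length(width),
            length(center) == length(amplitude))
  if (any(center < 0 | center >= 1)) abort("Bump centres must lie in [0, 1).")
  if (any(width <= 0)) abort("Bump widths must be positive.")
  if (any(amplitude < 0)) abort("Bump amplitudes must be non-negative.")
  tibble::tibble(center = center, width = width, amplitude = amplitude)
}

#' @rdname activation_template
#' @export
default_activation_templates <- function() {
  list(
    TA  = activation_template(center = c(0.78, 0.00),
                              width = c(0.06, 0.04),
                              amplitude = c(1.00, 0.35)),
    SOL = activation_template(0.35, 0.15, 0.80),
    LG  = activation_template(0.45, 0.08, 1.00),
    MG  = activation_template(0.45, 0.08, 1.00)
  )
}

#' @rdname activation_template
#' @param template A template tibble.
#' @param phase Phases at which to evaluate (wrapped into `[0, 1)`).
#' @export
eval_template <- function(template, phase) {
  phase <- phase %% 1
  out <- numeric(length(phase))
  for (i in seq_len(nrow(template))) {
    d <- abs(phase - template$center[i])
    d <- pmin(d, 1 - d)                       # wrapped (circular) distance
    out <- out + template$amplitude[i] * exp(-0.5 * (d / template$width[i])^2)
  }
  out
}

#' Parameters of the synthetic gait-EMG generator
#'
#' Bundles every knob of the generator. The defaults reproduce the study
#' conditions of the experiments the package targets: 2000 Hz sampling,
#' 10-500 Hz signal band, 15 s of walking per treadmill speed, speeds from
#' 1.0 to 4.5 km/h, and amplitudes that grow linearly with speed.
#'
#' @param fs Sampling rate (Hz).
#' @param duration Recording length (s).
#' @param speed Treadmill speed (km/h).
#' @param cycle_duration Gait-cycle length (s). Default `60 / (45 + 10 * speed)`,
#'   a cadence that rises with speed.
#' @param templates Named list of [activation_template()]s, one per muscle.
#' @param asymmetry Named multiplicative gains per channel
#'   (e.g. `c(left_SOL = 1.3)`); channels not named default to 1.
#' @param mvc_amplitude Named carrier scale per muscle in mV (the amplitude a
#'   maximum voluntary contraction would reach); unnamed scalar recycles.
#' @param speed_gain Fractional amplitude increase per km/h.
#' @param noise_band Two-element band (Hz) of the stochastic carrier; must
#'   lie inside `(0, fs/2)`.
#' @param baseline_level Resting activation floor as a fraction of the MVC
#'   carrier scale.
#' @param ripple Named per-channel relative amplitude (in `[0, 1]`) of a
#'   phase-locked sinusoidal modulation of the activation profile, used to
#'   inject extra envelope irregularity into selected channels.
#' @param ripple_per_cycle Ripple oscillations per gait cycle. The default
#'   of 2 is slow enough for the default 125 ms RMS envelope window to
#'   track even at the fastest cadence (a 0.67 s cycle spans only ~11
#'   envelope frames), so the injected irregularity survives into the
#'   phase-normalized curves.
#' @param muscles Muscles to generate (subset of [emg_muscles()]).
#' @param seed Integer seed; identical parameters (including the seed) give
#'   bit-identical recordings.
#' @param subject_id Subject label attached to generated recordings.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(fs = 2000, duration = 15, speed = 3,
                         cycle_duration = NULL,
                         templates = default_activation_templates(),
                         asymmetry = NULL,
                         mvc_amplitude = 0.5,
                         speed_gain = 0.15,
                         noise_band = c(10, 500),
                         baseline_level = 0.15,
                         ripple = NULL,
                         ripple_per_cycle = 2,
                         muscles = emg_muscles(),
                         seed = 1L,
                         subject_id = "synthetic") {
  if (duration <= 0) abort("`duration` must be positive.")
  if (length(noise_band) != 2L || noise_band[1] <= 0 ||
      noise_band[2] <= noise_band[1] || noise_band[2] >= fs / 2) {
    abort("`noise_band` must satisfy 0 < low < high < fs/2.")
  }
  cycle_duration <- cycle_duration %||% (60 / (45 + 10 * speed))
  if (cycle_duration <= 0) abort("`cycle_duration` must be positive.")
  muscles <- match.arg(muscles, emg_muscles(), several.ok = TRUE)
  chans <- intersect(canonical_channels(),
                     as.vector(outer(emg_sides(), muscles, paste, sep = "_")))
  asym <- setNames(rep(1, length(chans)), chans)
  if (!is.null(asymmetry)) {
    bad <- setdiff(names(asymmetry), chans)
    if (length(bad)) abort(paste0("Unknown asymmetry channel(s): ",
                                  paste(bad, collapse = ", ")))
    if (any(asymmetry < 0)) abort("Asymmetry gains must be >= 0.")
    asym[names(asymmetry)] <- asymmetry
  }
  amp <- if (is.null(names(mvc_amplitude))) {
    setNames(rep(mvc_amplitude[1], length(muscles)), muscles)
  } else {
    a <- setNames(rep(0.5, length(muscles)), muscles)
    a[intersect(names(mvc_amplitude), muscles)] <-
      mvc_amplitude[intersect(names(mvc_amplitude), muscles)]
    a
  }
  rip <- setNames(rep(0, length(chans)), chans)
  if (!is.null(ripple)) {
    bad <- setdiff(names(ripple), chans)
    if (length(bad)) abort(paste0("Unknown ripple channel(s): ",
                                  paste(bad, collapse = ", ")))
    if (any(ripple < 0 | ripple > 1)) abort("`ripple` must lie in [0, 1].")
    rip[names(ripple)] <- ripple
  }
  structure(list(fs = fs, duration = duration, speed = speed,
                 cycle_duration = cycle_duration, templates = templates,
                 asymmetry = asym, mvc_amplitude = amp,
                 speed_gain = speed_gain, noise_band = noise_band,
                 baseline_level = baseline_level, ripple = rip,
                 ripple_per_cycle = ripple_per_cycle,
                 muscles = muscles, channels = chans,
                 seed = as.integer(seed), subject_id = subject_id),
            class = "synth_params")
}

# zero-mean Gaussian noise band-limited to `band`, unit SD in expectation.
# Band-limiting is done by masking the discrete Fourier transform of white
# Gaussian noise, which confines the carrier's power exactly to the band
# (an ideal-filter surrogate); the result stays Gaussian because the
# operation is linear. Scaling uses the theoretical SD of the masked
# process (sqrt of the kept-bin fraction), not the realized sample SD:
# pinning each channel's realized power would suppress the natural
# between-channel power fluctuation and bias null statistics.
band_limited_noise <- function(n, fs, band) {
  x <- rnorm(n)
  xf <- fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)              # two-sided spectrum
  drop <- freq < band[1] | freq > band[2]
  xf[drop] <- 0
  y <- Re(fft(xf, inverse = TRUE)) / n
  y / sqrt(mean(!drop))
}

#' Simulate a multi-channel walking sEMG recording
#'
#' Each channel is \eqn{x(t) = A \cdot (b + e(\phi(t))) \cdot n(t)}, where
#' \eqn{n(t)} is zero-mean Gaussian noise band-limited to `noise_band` and
#' rescaled to unit SD, \eqn{e} the muscle's activation template evaluated at
#' gait phase \eqn{\phi(t) = (t \bmod T)/T} (phase 0 at right-TA activation
#' onset), \eqn{b} the resting floor `baseline_level`, and
#' \eqn{A = } `mvc_amplitude * asymmetry gain * (1 + speed_gain * speed)`.
#' When a channel has non-zero `ripple` \eqn{a}, its activation profile is
#' modulated as \eqn{e(\phi)(1 + a \sin(2\pi k \phi))} with
#' \eqn{k =} `ripple_per_cycle`.
#'
#' The returned recording carries a `ground_truth` attribute (see
#' [synth_ground_truth()]) with the true cycle onset times, the number of
#' complete cycles, and each channel's amplitude scale and expected mean
#' activation.
#'
#' @param params A [synth_params()] object.
#' @return An [emg_recording()] with a `ground_truth` attribute.
#' @export
#' @examples
#' rec <- synth_gait_emg(synth_params(duration = 4, speed = 3, seed = 7))
#' synth_ground_truth(rec)$n_cycles
synth_gait_emg <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  n <- round(p$duration * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  phase <- (t %% p$cycle_duration) / p$cycle_duration
  speed_factor <- 1 + p$speed_gain * p$speed
  cols <- list()
  truth <- list()
  for (ch in p$channels) {
    mus <- channel_muscle(ch)
    e <- eval_template(p$templates[[mus]], phase)
    shape <- p$baseline_level + e
    a <- p$ripple[[ch]]
    if (a > 0) {
      # phase-locked, so it survives ensemble averaging; slow enough
      # (few oscillations per cycle) to survive the RMS envelope bandwidth
      shape <- shape * (1 + a * sin(2 * pi * p$ripple_per_cycle * phase))
    }
    A <- p$mvc_amplitude[[mus]] * p$asymmetry[[ch]] * speed_factor
    cols[[ch]] <- A * shape * band_limited_noise(n, p$fs, p$noise_band)
    truth[[ch]] <- tibble::tibble(
      channel = ch, side = channel_side(ch), muscle = mus,
      gain = p$asymmetry[[ch]], amplitude = A,
      mean_activation = A * mean(shape))
  }
  rec <- emg_recording(cols, fs = p$fs, condition = p$speed,
                       subject_id = p$subject_id)
  onsets <- seq(0, p$duration - 1e-9, by = p$cycle_duration)
  attr(rec, "ground_truth") <- list(
    onset_times = onsets,
    n_cycles = length(onsets),
    cycle_duration = p$cycle_duration,
    channels = dplyr::bind_rows(truth))
  rec
}

#' @rdname synth_gait_emg
#' @param rec A synthetic recording.
#' @export
synth_ground_truth <- function(rec) attr(rec, "ground_truth")

#' Simulate a quiet-standing sEMG recording
#'
#' Stationary band-limited noise per channel with amplitude
#' `mvc_amplitude * asymmetry * baseline_level` -- the standing condition of
#' the protocol, where muscles hold a low tonic activation with no gait
#' phase structure. Activation templates, speed and ripple are ignored.
#'
#' @inheritParams synth_gait_emg
#' @return An [emg_recording()] with condition `"static"`.
#' @export
synth_static_emg <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  n <- round(p$duration * p$fs)
  cols <- list()
  for (ch in p$channels) {
    A <- p$mvc_amplitude[[channel_muscle(ch)]] * p$asymmetry[[ch]] *
      p$baseline_level
    cols[[ch]] <- if (A == 0) numeric(n) else
      A * band_limited_noise(n, p$fs, p$noise_band)
  }
  emg_recording(cols, fs = p$fs, condition = "static",
                subject_id = p$subject_id)
}

#' Simulate a maximum-voluntary-contraction reference trial
#'
#' Band-limited noise at the full per-muscle carrier amplitude for both
#' sides of one muscle. MVC trials serve as the normalization reference:
#' downstream, envelopes are expressed as a percentage of the MVC envelope
#' peak (see [extract_mvc()] and [mvc_normalize()]).
#'
#' @param muscle One of [emg_muscles()].
#' @param mvc_amplitude Carrier amplitude (mV) for both sides, or a named
#'   vector `c(left = ..., right = ...)`.
#' @param fs Sampling rate (Hz).
#' @param duration Trial length (s); must be at least 1 s.
#' @param seed Integer seed.
#' @param noise_band Carrier band (Hz).
#' @return An [emg_recording()] with the muscle's two channels.
#' @export
synth_mvc_trial <- function(muscle, mvc_amplitude = 0.5, fs = 2000,
                            duration = 5, seed = 1L,
                            noise_band = c(10, 500)) {
  muscle <- match.arg(muscle, emg_muscles())
  if (duration < 1) abort("An MVC trial must last at least 1 s.")
  amp <- if (is.null(names(mvc_amplitude))) {
    c(left = mvc_amplitude[1], right = mvc_amplitude[1])
  } else {
    c(left = unname(mvc_amplitude["left"]),
      right = unname(mvc_amplitude["right"]))
  }
  set.seed(as.integer(seed))
  n <- round(duration * fs)
  cols <- list()
  for (side in emg_sides()) {
    ch <- paste(side, muscle, sep = "_")
    cols[[ch]] <- if (amp[[side]] == 0) numeric(n) else
      amp[[side]] * band_limited_noise(n, fs, noise_band)
  }
  emg_recording(cols, fs = fs, condition = "static", subject_id = "mvc")
}

#' Build an MVC reference from synthetic trials
#'
#' Convenience wrapper: simulates one MVC trial per muscle of `params` and
#' extracts the reference envelope peak for every channel through the same
#' preprocessing path used for the experiments.
#'
#' @param params A [synth_params()] object.
#' @param window,overlap RMS envelope settings passed to [rms_envelope()].
#' @return An MVC reference tibble (see [extract_mvc()]).
#' @export
synth_mvc_reference <- function(params, window = 0.125, overlap = 0.5) {
  stopifnot(inherits(params, "synth_params"))
  refs <- purrr::map(params$muscles, function(mus) {
    trial <- synth_mvc_trial(mus, mvc_amplitude = params$mvc_amplitude[[mus]],
                             fs = params$fs, seed = params$seed + 1000L +
                               match(mus, emg_muscles()),
                             noise_band = params$noise_band)
    extract_mvc(rms_envelope(trial, window = window, overlap = overlap))
  })
  dplyr::bind_rows(refs)
}
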